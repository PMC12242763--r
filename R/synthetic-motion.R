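#' Biphasic cycle shape function
#'
#' Smooth reservoir/conduit/booster phase template on `[0, 1)`: 0 at LVED
#' (frame 0), raised-cosine rise to 1 at the reservoir peak (`t_peak`),
#' fall to a conduit plateau, then booster return to 0. Periodic by
#' construction.
#'
#' @param t cycle fractions in `[0, 1)`.
#' @param t_peak reservoir peak phase (default 0.45).
#' @param conduit_level residual filling fraction after the conduit phase
#'   (default 0.35).
#' @param t_conduit end of the conduit phase (default 0.72).
#' @return values in `[0, 1]`, 0 at `t = 0`.
#' @export
cycle_shape <- function(t, t_peak = 0.45, conduit_level = 0.35,
                        t_conduit = 0.72) {
  ramp <- function(x) 0.5 * (1 - cos(pi * pmin(pmax(x, 0), 1)))
  out <- numeric(length(t))
  r <- t <= t_peak
  out[r] <- ramp(t[r] / t_peak)
  cnd <- t > t_peak & t <= t_conduit
  out[cnd] <- 1 - (1 - conduit_level) * ramp((t[cnd] - t_peak) /
                                               (t_conduit - t_peak))
  bst <- t > t_conduit
  out[bst] <- conduit_level * (1 - ramp((t[bst] - t_conduit) /
                                          (1 - t_conduit)))
  out
}

#' Generate cyclic mesh motion for a synthetic subject
#'
#' Deforms the anatomy through one cardiac cycle starting at LVED (minimum
#' volume). Each vertex moves radially about the body centroid with a
#' region-specific amplitude following the biphasic [cycle_shape]; the
#' amplitudes are calibrated so the measured regional reservoir strains
#' match the per-region targets. Because the radial field is monotone in
#' the shape function, frame 0 remains the volume minimum and the emptying
#' fraction emerges from the strain pattern (bounded by the isoperimetric
#' relation; see the methods vignette). Optional uncorrelated vertex jitter
#' (`spec$motion_jitter_sd`) is added to all frames after the first.
#'
#' @param anatomy an [la_mesh] from [generate_anatomy].
#' @param spec a [cohort_spec].
#' @param subject_seed integer seed.
#' @param regions vertex region factor from [assign_regions]; computed from
#'   a default parameterization when missing.
#' @param rs_targets optional named per-region reservoir-strain targets (%);
#'   drawn from the spec when `NULL`.
#' @param uniform_lambda if non-`NULL`, ignore the targets and apply pure
#'   uniform scaling with peak factor `uniform_lambda` (analytic oracle
#'   mode).
#' @return a [mesh_motion] with attribute `truth`: noise-free per-region
#'   strain curves, reservoir strains, and the volume curve with LAV/LAEF.
#' @export
generate_motion <- function(anatomy, spec, subject_seed = 1L, regions = NULL,
                            rs_targets = NULL, uniform_lambda = NULL) {
  set.seed(subject_seed)
  nf <- spec$frames_per_cycle
  tt <- (seq_len(nf) - 1) / nf
  g <- cycle_shape(tt)
  v0 <- anatomy$vertices
  body <- anatomy$labels %in% c("body", "mitral_rim")
  ctr <- colMeans(v0[body, , drop = FALSE])
  if (!is.null(uniform_lambda)) {
    sv <- rep(uniform_lambda, nrow(v0))
  } else {
    if (is.null(regions)) {
      uac <- build_uac(anatomy)
      regions <- assign_regions(anatomy, uac, spec$antra_radius)
    }
    if (is.null(rs_targets)) rs_targets <- draw_rs_targets(spec)
    if (is.null(names(rs_targets))) names(rs_targets) <- la_regions()
    # non-body vertices inherit the nearest body vertex's region
    reg_all <- as.integer(regions)
    nb <- which(is.na(reg_all))
    if (length(nb)) {
      bidx <- which(!is.na(reg_all))
      nn <- nearest_rows(v0[nb, , drop = FALSE], v0[bidx, , drop = FALSE])
      reg_all[nb] <- reg_all[bidx[nn]]
    }
    sv <- calibrate_motion(anatomy, reg_all, regions, rs_targets, ctr)
  }
  rel <- sweep(v0, 2, ctr, "-")
  frames <- lapply(seq_len(nf), function(i)
    sweep(rel * (1 + (sv - 1) * g[i]), 2, ctr, "+"))
  motion0 <- mesh_motion(anatomy, frames, frame_times = tt)
  truth <- list(rs_targets = if (is.null(uniform_lambda)) rs_targets)
  if (is.null(uniform_lambda)) {
    es <- area_strain(motion0)
    sc <- regional_strain_curves(es, regions, motion0)
    vc <- volume_curve(motion0)
    truth$curves <- sc
    truth$rs <- apply(sc$regional, 1, function(c) max(c) - min(c))
    truth$global_rs <- max(sc$global) - min(sc$global)
    truth$volume <- vc
  }
  if (spec$motion_jitter_sd > 0) {
    for (i in 2:nf)
      frames[[i]] <- frames[[i]] +
        matrix(stats::rnorm(length(v0), 0, spec$motion_jitter_sd),
               ncol = 3)
  }
  motion <- mesh_motion(anatomy, frames, frame_times = tt)
  attr(motion, "truth") <- truth
  motion
}

# fixed-point calibration of the per-region radial scale factors against the
# regional reservoir-strain targets, measured at the cycle peak (the radial
# field is monotone in the cycle shape, so the peak is the extremum)
calibrate_motion <- function(anatomy, reg_all, regions, rs_targets, ctr,
                             n_iter = 6L) {
  v0 <- anatomy$vertices
  rel <- sweep(v0, 2, ctr, "-")
  a0 <- triangle_areas(anatomy)
  treg <- triangle_regions(anatomy, regions)
  lev <- la_regions()
  reg_area0 <- vapply(lev, function(r) sum(a0[which(treg == r)]), numeric(1))
  ratio_tgt <- 1 + rs_targets[lev] / 100
  s_reg <- sqrt(ratio_tgt)
  for (it in seq_len(n_iter)) {
    sv <- s_reg[reg_all]
    at <- triangle_areas(sweep(rel * sv, 2, ctr, "+"), anatomy$triangles)
    meas <- vapply(lev, function(r) sum(at[which(treg == r)]),
                   numeric(1)) / reg_area0
    # every region expands during the reservoir phase: scales below 1 would
    # turn the amplitude (max - min) into the negative excursion and the
    # fixed point runs away, so clamp to expansion only
    s_reg <- pmin(2.5, pmax(1, s_reg * sqrt(ratio_tgt / meas)))
  }
  # narrow regions bordered by much stronger neighbours can stay above
  # target even at the clamp (vertex-based amplitudes mix across region
  # boundaries); a final global amplitude factor restores the subject's
  # mean reservoir strain so pooled cohort means remain calibrated
  mean_rs <- function(c) {
    sv <- 1 + (s_reg[reg_all] - 1) * c
    at <- triangle_areas(sweep(rel * sv, 2, ctr, "+"), anatomy$triangles)
    meas <- vapply(lev, function(r) sum(at[which(treg == r)]),
                   numeric(1)) / reg_area0
    mean(100 * (meas - 1))
  }
  tgt_mean <- mean(rs_targets[lev])
  c1 <- 1; f1 <- mean_rs(1) - tgt_mean
  if (abs(f1) > 0.2) {
    c0 <- 0.9; f0 <- mean_rs(0.9) - tgt_mean
    for (step in 1:3) {
      if (abs(f1 - f0) < 1e-9) break
      c2 <- max(0.3, min(1.6, c1 - f1 * (c1 - c0) / (f1 - f0)))
      c0 <- c1; f0 <- f1
      c1 <- c2; f1 <- mean_rs(c2) - tgt_mean
      if (abs(f1) < 0.1) break
    }
  }
  1 + (s_reg[reg_all] - 1) * c1
}

# closed-form divergence-theorem volume evaluator reusing the capped
# connectivity; returns a function of replacement vertex positions
fast_volume_fun <- function(mesh,
                            exclude = c("LAA", "LSPV", "LIPV", "RSPV",
                                        "RIPV")) {
  ex <- mesh$labels %in% exclude
  tri <- mesh$triangles
  keep <- !(ex[tri[, 1]] | ex[tri[, 2]] | ex[tri[, 3]])
  sm <- submesh(mesh, keep)
  loops <- boundary_loops(sm$mesh$triangles)
  f <- sm$mesh$triangles
  nbase <- nrow(sm$mesh$vertices)
  loop_ids <- list()
  for (lp in loops) {
    ci <- nbase + length(loop_ids) + 1L
    loop_ids[[length(loop_ids) + 1L]] <- lp
    nxt <- c(lp[-1], lp[1])
    f <- rbind(f, cbind(nxt, lp, ci))
  }
  vmap <- sm$vertex_map
  function(vertices) {
    v <- vertices[vmap, , drop = FALSE]
    for (lp in loop_ids)
      v <- rbind(v, colMeans(v[lp, , drop = FALSE]))
    v0 <- v[f[, 1], , drop = FALSE]
    v1 <- v[f[, 2], , drop = FALSE]
    v2 <- v[f[, 3], , drop = FALSE]
    det6 <- v0[, 1] * (v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2]) -
      v0[, 2] * (v1[, 1] * v2[, 3] - v1[, 3] * v2[, 1]) +
      v0[, 3] * (v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
    abs(sum(det6)) / 6 / 1000
  }
}
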