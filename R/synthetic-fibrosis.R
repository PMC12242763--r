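#' Generate a synthetic LGE-like intensity field with known regional truth
#'
#' Draws each region's severe-fibrosis status from a logistic model whose
#' log-odds are `intercept_r + link_lav * z(LAV) + link_laef * z(LAEF)`
#' (plus `strain_fibrosis_coupling * z(RS)` when the coupling knob is on),
#' draws a target enhancement fraction consistent with that status from the
#' region's burden distribution, then paints contiguous enhanced patches on
#' the region until the above-threshold area fraction matches the target.
#' Enhanced vertices receive intensity ratios in (1.45, 1.70) times the
#' blood-pool mean and quiescent vertices (0.75, 0.94), so the 1.2
#' image-intensity-ratio threshold separates them exactly in the noise-free
#' field; Gaussian noise (`spec$intensity_noise_sd`, relative) is added on
#' top.
#'
#' @param anatomy an [la_mesh].
#' @param regions vertex region factor from [assign_regions].
#' @param global_measures list with `lav` (mL) and `laef` (%) for the link
#'   model.
#' @param spec a [cohort_spec].
#' @param subject_seed integer seed.
#' @param rs_targets per-region reservoir strains (%), used only when
#'   `strain_fibrosis_coupling != 0`.
#' @param config a [fibrosis_config] (threshold and triangle rule used for
#'   painting bookkeeping).
#' @return list with `vertex_intensity`, `blood_pool_mean`, and `truth`
#'   (data.frame: region, target_pct, enhancement_pct, stage, severe).
#' @export
generate_fibrosis <- function(anatomy, regions, global_measures, spec,
                              subject_seed = 1L, rs_targets = NULL,
                              config = fibrosis_config()) {
  set.seed(subject_seed)
  lev <- la_regions()
  if (any(is.na(match(lev, levels(regions)))) ||
      any(!lev %in% regions[!is.na(regions)]))
    stop("all six regions must be present")
  z_lav <- (global_measures$lav - spec$lav_mean) / spec$lav_sd
  z_laef <- (global_measures$laef - spec$laef_mean) / spec$laef_sd
  # intercepts solving the logistic-normal marginal exactly: find a with
  # E[plogis(a + sigma Z)] = target prevalence, Z standard normal
  sigma <- sqrt(spec$link_lav^2 + spec$link_laef^2 +
                  spec$strain_fibrosis_coupling^2)
  a_r <- vapply(pmin(pmax(spec$severe_prevalence[lev], 1e-4), 1 - 1e-4),
                intercept_for_prevalence, numeric(1), sigma = sigma)
  eta <- a_r + spec$link_lav * z_lav + spec$link_laef * z_laef
  if (spec$strain_fibrosis_coupling != 0) {
    if (is.null(rs_targets)) stop("rs_targets needed when coupling is active")
    z_rs <- (rs_targets[lev] - spec$rs_mean) / spec$rs_sd
    eta <- eta + spec$strain_fibrosis_coupling * z_rs
  }
  severe <- stats::runif(6) < stats::plogis(eta)
  mu <- spec$fibrosis_region_mu[lev]
  sd <- spec$fibrosis_region_sd[lev]
  target <- numeric(6)
  for (i in 1:6) {
    target[i] <- if (severe[i]) rtruncnorm(1, mu[i], sd[i], 31.5, 92)
    else if (mu[i] <= 0) 0
    else rtruncnorm(1, mu[i], sd[i], 0.5, 28.5)
  }
  paint <- paint_enhancement(anatomy, regions, target / 100)
  ratio <- ifelse(paint$enhanced,
                  stats::runif(nrow(anatomy$vertices), 1.45, 1.70),
                  stats::runif(nrow(anatomy$vertices), 0.75, 0.94))
  bp <- spec$blood_pool_mean
  intensity <- ratio * bp +
    stats::rnorm(length(ratio), 0, spec$intensity_noise_sd * bp)
  st <- stage_enhancement(100 * paint$achieved, config)
  truth <- data.frame(region = factor(lev, levels = lev),
                      target_pct = target,
                      enhancement_pct = 100 * paint$achieved,
                      stage = st$stage, severe = st$severe)
  if (!all(truth$severe == severe))
    stop("painting failed to realize the drawn severe status")
  list(vertex_intensity = as.numeric(intensity), blood_pool_mean = bp,
       truth = truth)
}

# solve E[plogis(a + sigma Z)] = p for the intercept a (Gauss-Hermite-free:
# adaptive quadrature is cheap at this scale)
intercept_for_prevalence <- function(p, sigma) {
  marginal <- function(a)
    stats::integrate(function(x) stats::plogis(a + sigma * x) *
                       stats::dnorm(x), -8, 8, rel.tol = 1e-8)$value
  stats::uniroot(function(a) marginal(a) - p,
                 c(-30, 30), tol = 1e-6)$root
}

# grow contiguous enhanced patches per region until the enhanced area
# fraction (triangle rule: >= 2 of 3 vertices enhanced, consistent with the
# intensity draw ranges and the 1.2 IIR threshold) matches the target. A
# reconciliation phase then re-evaluates every region against the global
# enhanced field -- patches spill across region boundaries through shared
# triangles -- and nudges each region back onto its side of the 30% staging
# boundary.
paint_enhancement <- function(mesh, regions, target_frac) {
  lev <- la_regions()
  n <- nrow(mesh$vertices)
  treg <- triangle_regions(mesh, regions)
  areas <- triangle_areas(mesh)
  adj <- vertex_adjacency(mesh)
  tri <- mesh$triangles
  rtris <- lapply(lev, function(r) which(treg == r))
  rverts <- lapply(lev, function(r) which(!is.na(regions) & regions == r))
  if (any(lengths(rtris) == 0L) || any(lengths(rverts) == 0L))
    stop("empty region: ", lev[which(lengths(rtris) == 0L | lengths(rverts)
                                     == 0L)][1])
  rtot <- vapply(rtris, function(ix) sum(areas[ix]), numeric(1))
  enhanced <- rep(FALSE, n)
  painted <- vector("list", 6)   # per-region own painted vertices, in order
  frac_of <- function(r) {
    ix <- rtris[[r]]
    cnt <- matrix(enhanced[tri[ix, , drop = FALSE]], ncol = 3)
    sum(areas[ix][rowSums(cnt) >= 2L]) / rtot[r]
  }
  lo_req <- ifelse(target_frac > 0.30, 0.308, -1)
  hi_req <- ifelse(target_frac > 0.30, 1, 0.292)
  grow_one <- function(r) {
    vs <- rverts[[r]]
    cand <- vs[!enhanced[vs]]
    if (!length(cand)) return(FALSE)
    nb <- unique(unlist(adj[painted[[r]]]))
    nb <- nb[nb %in% cand]
    vtx <- if (length(nb)) nb[sample.int(length(nb), 1)]
    else cand[sample.int(length(cand), 1)]
    enhanced[vtx] <<- TRUE
    painted[[r]] <<- c(painted[[r]], vtx)
    TRUE
  }
  drop_one <- function(r) {
    if (!length(painted[[r]])) return(FALSE)
    vtx <- painted[[r]][length(painted[[r]])]
    enhanced[vtx] <<- FALSE
    painted[[r]] <<- painted[[r]][-length(painted[[r]])]
    TRUE
  }
  # phase 1: greedy growth toward each region target
  for (r in seq_along(lev)) {
    tgt <- target_frac[r]
    if (tgt <= 1e-6) next
    vs <- rverts[[r]]
    n_patch <- 1L + (stats::runif(1) < 0.4)
    frontier <- vs[sample.int(length(vs), min(n_patch, length(vs)))]
    prev_err <- tgt
    repeat {
      while (length(frontier) && enhanced[frontier[1]])
        frontier <- frontier[-1]
      if (!length(frontier)) {
        cand <- vs[!enhanced[vs]]
        if (!length(cand)) break
        frontier <- cand[sample.int(length(cand), 1)]
      }
      vtx <- frontier[1]
      frontier <- frontier[-1]
      enhanced[vtx] <- TRUE
      painted[[r]] <- c(painted[[r]], vtx)
      nb <- adj[[vtx]]
      nb <- nb[nb %in% vs & !enhanced[nb]]
      if (length(nb)) frontier <- c(frontier, nb[sample.int(length(nb))])
      fr <- frac_of(r)
      err <- abs(fr - tgt)
      if (fr >= tgt) {
        if (err > prev_err) {
          drop_one(r)
          if (frac_of(r) <= lo_req[r]) grow_one(r)
        }
        break
      }
      prev_err <- err
    }
  }
  # phase 2: reconcile against cross-region spill
  for (pass in 1:4) {
    moved <- FALSE
    for (r in seq_along(lev)) {
      guard <- 0L
      while (frac_of(r) <= lo_req[r] && guard < 500L) {
        if (!grow_one(r)) break
        moved <- TRUE
        guard <- guard + 1L
      }
      guard <- 0L
      while (frac_of(r) > hi_req[r] && guard < 500L) {
        if (!drop_one(r)) break
        moved <- TRUE
        guard <- guard + 1L
      }
    }
    if (!moved) break
  }
  achieved <- vapply(seq_along(lev), frac_of, numeric(1))
  list(enhanced = enhanced, achieved = achieved)
}
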