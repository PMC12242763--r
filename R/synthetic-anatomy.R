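#' Generate a labelled synthetic LA anatomy
#'
#' Builds an ellipsoidal atrial body from a subdivided icosphere, opens the
#' mitral orifice, extrudes four pulmonary-vein stubs and an appendage stub
#' along fixed anatomical directions, labels every vertex, records the
#' PV--LA junction rings and the four harmonic-coordinate anchor sets as
#' landmarks, and rescales the whole shape so the body volume (LAA and PVs
#' excluded) matches `volume_target`.
#'
#' Canonical frame: +x septal, -x lateral, +y anterior, -y posterior,
#' -z mitral.
#'
#' @param spec a [cohort_spec].
#' @param subject_seed integer seed (bitwise reproducible output).
#' @param volume_target body volume in mL at this (LVED, minimum-volume)
#'   frame; if `NULL`, drawn from the spec's LAV/LAEF distributions.
#' @return an [la_mesh] passing all mesh invariants.
#' @export
generate_anatomy <- function(spec, subject_seed = 1L, volume_target = NULL) {
  set.seed(subject_seed)
  if (is.null(volume_target)) {
    lav <- rtruncnorm(1, spec$lav_mean, spec$lav_sd,
                      spec$lav_range[1], spec$lav_range[2])
    laef <- rtruncnorm(1, spec$laef_mean, spec$laef_sd, 10, 82)
    volume_target <- lav * (1 - laef / 100)
  }
  base <- icosphere(spec$mesh_subdiv)
  u <- base$vertices                      # unit-sphere positions
  f <- base$triangles
  dirs <- rbind(
    LSPV = c(-0.75, -0.45, 0.55), LIPV = c(-0.80, -0.55, -0.05),
    RSPV = c(0.75, -0.45, 0.55), RIPV = c(0.80, -0.55, -0.05),
    LAA  = c(-0.55, 0.70, 0.45))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  cap_deg <- c(LSPV = 13, LIPV = 13, RSPV = 13, RIPV = 13, LAA = 16)
  stub_len <- c(LSPV = 9, LIPV = 9, RSPV = 9, RIPV = 9, LAA = 11)
  ang <- acos(pmin(pmax(u %*% t(dirs), -1), 1))   # n x 5 angles to centres
  labels <- rep("body", nrow(u))
  for (k in seq_len(nrow(dirs))) {
    inside <- ang[, k] < cap_deg[k] * pi / 180
    labels[inside] <- rownames(dirs)[k]
  }
  # open the mitral orifice
  mit_ang <- acos(pmax(-1, pmin(1, -u[, 3])))
  in_mit <- mit_ang < 36 * pi / 180
  drop_tri <- in_mit[f[, 1]] & in_mit[f[, 2]] & in_mit[f[, 3]]
  sm <- submesh(la_mesh(u, f, labels, validate = FALSE), !drop_tri)
  u <- sm$mesh$vertices
  f <- sm$mesh$triangles
  labels <- sm$mesh$labels
  rim <- unique(unlist(boundary_loops(f)))
  labels[rim] <- "mitral_rim"
  # ellipsoid semi-axes with mild per-subject shape variation
  axes <- c(27, 23, 33) *
    pmin(pmax(1 + stats::rnorm(3, 0, 0.05), 0.88), 1.12)
  v <- sweep(u, 2, axes, "*")
  # extrude stubs along the cap-centre outward direction
  for (k in seq_len(nrow(dirs))) {
    lab <- rownames(dirs)[k]
    sel <- labels == lab
    if (!any(sel)) stop("stub cap produced no vertices: ", lab)
    e <- dirs[k, ] * axes
    e <- e / sqrt(sum(e^2))
    a <- acos(pmin(1, pmax(-1, u[sel, , drop = FALSE] %*% dirs[k, ])))
    prof <- (1 - (a / (cap_deg[k] * pi / 180))^2)^0.8
    v[sel, ] <- v[sel, ] + outer(as.numeric(prof) * stub_len[k], e)
  }
  # landmarks: junction rings = body vertices sharing an edge with a stub
  edges <- mesh_edges(la_mesh(v, f, validate = FALSE))
  landmarks <- list(mitral_ring = which(labels == "mitral_rim"))
  for (lab in rownames(dirs)) {
    on <- labels[edges[, 1]] == lab | labels[edges[, 2]] == lab
    ring <- unique(c(edges[on, 1], edges[on, 2]))
    ring <- ring[labels[ring] == "body"]
    if (!length(ring)) stop("empty junction ring for ", lab)
    landmarks[[paste0(lab, "_junction")]] <- sort(ring)
  }
  anchor_dirs <- rbind(lateral_anchor = c(-1, 0, 0),
                       septal_anchor = c(1, 0, 0),
                       posterior_anchor = c(0, -1, 0),
                       anterior_anchor = c(0, 1, 0))
  aang <- acos(pmin(pmax(u %*% t(anchor_dirs), -1), 1))
  for (k in seq_len(nrow(anchor_dirs))) {
    sel <- which(aang[, k] < 12 * pi / 180 & labels == "body")
    if (!length(sel)) stop("empty anchor set")
    landmarks[[rownames(anchor_dirs)[k]]] <- sel
  }
  mesh <- la_mesh(v, f, labels, landmarks)
  vol <- enclosed_volume(mesh)
  mesh$vertices <- mesh$vertices * (volume_target / vol)^(1 / 3)
  attr(mesh, "volume_target") <- volume_target
  mesh
}
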