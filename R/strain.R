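#' Vertex-corresponded mesh motion over one cardiac cycle
#'
#' Frame 0 is the reference configuration at the left-ventricular
#' end-diastolic (LVED) timepoint, the atrial minimum-volume phase; all
#' frames share the reference connectivity.
#'
#' @param reference an [la_mesh] (the LVED frame).
#' @param frames list of n x 3 vertex-position matrices, one per timepoint;
#'   `frames[[1]]` must equal the reference positions.
#' @param frame_times numeric vector of cycle fractions in `[0, 1)`;
#'   defaults to a uniform grid.
#' @return object of class `mesh_motion`.
#' @export
mesh_motion <- function(reference, frames, frame_times = NULL) {
  nf <- length(frames)
  if (nf < 3L) stop("a motion sequence needs at least 3 frames")
  n <- nrow(reference$vertices)
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n, logical(1))
  if (!all(ok)) stop("all frames must share the reference connectivity")
  if (max(abs(frames[[1]] - reference$vertices)) > 1e-9)
    stop("frame 0 must equal the reference mesh")
  if (is.null(frame_times)) frame_times <- (seq_len(nf) - 1) / nf
  if (length(frame_times) != nf || is.unsorted(frame_times, strictly = TRUE) ||
      any(frame_times < 0) || any(frame_times >= 1))
    stop("frame_times must be strictly increasing in [0, 1)")
  structure(list(reference = reference, frames = frames,
                 frame_times = as.numeric(frame_times)),
            class = "mesh_motion")
}

#' @export
print.mesh_motion <- function(x, ...) {
  cat("<mesh_motion> ", length(x$frames), " frames, ",
      nrow(x$reference$vertices), " vertices\n", sep = "")
  invisible(x)
}

#' Per-element area strain curves
#'
#' Area strain of element e at frame t is
#' `100 * (A_e(t) - A_e(0)) / A_e(0)` with the LVED frame as reference, so
#' every curve starts at 0.
#'
#' @param motion a [mesh_motion].
#' @return m x nframes matrix of strains in percent (class
#'   `element_strains`, with the reference areas as attribute `ref_areas`).
#' @export
area_strain <- function(motion) {
  ref <- motion$reference
  a0 <- triangle_areas(ref)
  if (any(a0 <= 0)) stop("zero reference triangle area")
  s <- vapply(motion$frames, function(vf) {
    at <- triangle_areas(vf, ref$triangles)
    100 * (at - a0) / a0
  }, numeric(length(a0)))
  structure(s, ref_areas = a0, class = c("element_strains", "matrix"))
}

#' Regional and global area strain curves
#'
#' The regional curve is the strain of the summed regional area,
#' `100 * (sum A_e(t) - sum A_e(0)) / sum A_e(0)` (ratio of sums, the
#' default), or alternatively the reference-area-weighted mean of element
#' strains (`method = "mean_of_elements"`). The global curve covers all
#' body elements.
#'
#' @param element_strains result of [area_strain].
#' @param regions vertex region factor from [assign_regions].
#' @param motion the [mesh_motion] the strains came from.
#' @param method `"ratio_of_sums"` (default) or `"mean_of_elements"`.
#' @return object of class `strain_curves`: list with `regional`
#'   (6 x nframes matrix), `global` (vector), `frame_times`, `method`.
#' @export
regional_strain_curves <- function(element_strains, regions, motion,
                                   method = c("ratio_of_sums",
                                              "mean_of_elements")) {
  method <- match.arg(method)
  ref <- motion$reference
  a0 <- attr(element_strains, "ref_areas")
  treg <- triangle_regions(ref, regions)
  lev <- la_regions()
  if (any(!lev %in% levels(treg))) stop("regions factor must use la_regions()")
  body <- !is.na(treg)
  if (!any(body)) stop("no body triangles")
  nf <- ncol(element_strains)
  reg <- matrix(NA_real_, length(lev), nf, dimnames = list(lev, NULL))
  at <- element_strains / 100 * a0 + a0   # per-frame areas
  for (r in lev) {
    sel <- which(treg == r)
    if (!length(sel)) stop("empty region: ", r)
    if (method == "ratio_of_sums") {
      s0 <- sum(a0[sel])
      reg[r, ] <- 100 * (colSums(at[sel, , drop = FALSE]) - s0) / s0
    } else {
      w <- a0[sel] / sum(a0[sel])
      reg[r, ] <- colSums(element_strains[sel, , drop = FALSE] * w)
    }
  }
  s0 <- sum(a0[body])
  glob <- 100 * (colSums(at[body, , drop = FALSE]) - s0) / s0
  structure(list(regional = reg, global = glob,
                 frame_times = motion$frame_times, method = method),
            class = "strain_curves")
}

#' @export
print.strain_curves <- function(x, ...) {
  rs <- apply(x$regional, 1, function(c) max(c) - min(c))
  cat("<strain_curves> ", ncol(x$regional), " frames; reservoir strain (%):\n",
      sep = "")
  print(round(rs, 1))
  cat("  global RS: ", round(max(x$global) - min(x$global), 1), "%\n", sep = "")
  invisible(x)
}

#' Plot strain curves
#' @param x a `strain_curves` object.
#' @param ... passed to [graphics::matplot].
#' @export
plot.strain_curves <- function(x, ...) {
  graphics::matplot(x$frame_times, t(x$regional), type = "l", lty = 1,
                    xlab = "cycle fraction", ylab = "area strain (%)", ...)
  graphics::lines(x$frame_times, x$global, lwd = 3)
  graphics::legend("topright", legend = c(rownames(x$regional), "global"),
                   col = c(seq_len(nrow(x$regional)), 1),
                   lty = 1, lwd = c(rep(1, nrow(x$regional)), 3), cex = 0.7)
  invisible(x)
}

#' Per-element fibre strain curves
#'
#' Builds the in-plane deformation gradient of each triangle from its edge
#' vectors and reports the engineering stretch of the fibre direction:
#' `100 * (|F f| / |f| - 1)` with `f` expressed in the reference plane.
#'
#' @param motion a [mesh_motion].
#' @param fibres m x 3 matrix of per-triangle unit fibre vectors, tangent to
#'   the reference triangles.
#' @return m x nframes matrix of fibre strains in percent.
#' @export
fibre_strain <- function(motion, fibres) {
  ref <- motion$reference
  tri <- ref$triangles
  v0 <- ref$vertices
  e1 <- v0[tri[, 2], , drop = FALSE] - v0[tri[, 1], , drop = FALSE]
  e2 <- v0[tri[, 3], , drop = FALSE] - v0[tri[, 1], , drop = FALSE]
  # fibre in edge coordinates: f = w1 e1 + w2 e2 (least squares in-plane)
  g11 <- rowSums(e1 * e1); g12 <- rowSums(e1 * e2); g22 <- rowSums(e2 * e2)
  det <- g11 * g22 - g12^2
  if (any(det <= 0)) stop("degenerate triangle")
  b1 <- rowSums(fibres * e1); b2 <- rowSums(fibres * e2)
  w1 <- (g22 * b1 - g12 * b2) / det
  w2 <- (g11 * b2 - g12 * b1) / det
  l0 <- sqrt(rowSums((e1 * w1 + e2 * w2)^2))
  if (any(l0 < 1e-12)) stop("fibre not in triangle plane")
  out <- vapply(motion$frames, function(vf) {
    f1 <- vf[tri[, 2], , drop = FALSE] - vf[tri[, 1], , drop = FALSE]
    f2 <- vf[tri[, 3], , drop = FALSE] - vf[tri[, 1], , drop = FALSE]
    lt <- sqrt(rowSums((f1 * w1 + f2 * w2)^2))
    100 * (lt / l0 - 1)
  }, numeric(nrow(tri)))
  out
}

#' Volume curve, LAV and LAEF from mesh motion
#'
#' Computes the per-frame enclosed chamber volume with the appendage and
#' pulmonary veins excluded, and the emptying fraction
#' `LAEF = 100 * (LAV_max - LAV_min) / LAV_max`.
#'
#' @param motion a [mesh_motion].
#' @param exclude labels excluded before capping (default LAA + 4 PVs).
#' @return list with `lav` (mL per frame), `frame_times`, `lav_max`,
#'   `lav_min`, `laef` (%).
#' @export
volume_curve <- function(motion,
                         exclude = c("LAA", "LSPV", "LIPV", "RSPV", "RIPV")) {
  ref <- motion$reference
  lav <- vapply(motion$frames, function(vf) {
    m <- ref
    m$vertices <- vf
    enclosed_volume(m, exclude = exclude)
  }, numeric(1))
  lav_max <- max(lav); lav_min <- min(lav)
  if (lav_min <= 0) stop("non-positive chamber volume")
  list(lav = lav, frame_times = motion$frame_times,
       lav_max = lav_max, lav_min = lav_min,
       laef = 100 * (lav_max - lav_min) / lav_max)
}

#' Resample a cyclic curve onto a uniform grid
#'
#' Periodic linear interpolation onto `n_frames` uniform phase points in
#' `[0, 1)`; the value at phase 0 is preserved exactly. Used to align curves
#' acquired with different frame counts (20--50 across cohorts) onto the
#' common 30-frame grid.
#'
#' @param curve numeric vector of samples.
#' @param frame_times cycle fractions of the samples in `[0, 1)`.
#' @param n_frames target number of uniform frames (>= 3).
#' @return numeric vector of length `n_frames`.
#' @export
resample_curve <- function(curve, frame_times = NULL, n_frames = 30L) {
  if (length(curve) < 3L) stop("need at least 3 input frames")
  if (n_frames < 3L) stop("n_frames must be >= 3")
  if (is.null(frame_times)) frame_times <- (seq_along(curve) - 1) / length(curve)
  if (anyDuplicated(frame_times)) stop("duplicate frame times")
  tt <- c(frame_times, frame_times[1] + 1)
  yy <- c(curve, curve[1])
  tout <- (seq_len(n_frames) - 1) / n_frames
  stats::approx(tt, yy, xout = tout, method = "linear", rule = 2)$y
}
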