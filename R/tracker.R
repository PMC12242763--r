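#' Simplified surface motion tracker
#'
#' Establishes vertex correspondence between a reference LA surface and a
#' sequence of uncorresponded target surfaces of the same anatomy. This is a
#' deliberately simple surface tracker -- iterative closest-point
#' correspondence with Laplacian-smoothed displacement increments,
#' propagated frame to frame -- intended for tracking smooth chamber
#' deformations, not a general image-registration method.
#'
#' @param reference an [la_mesh] at the LVED timepoint.
#' @param target_surfaces list of meshes (or n x 3 vertex matrices), one per
#'   frame; connectivity may differ from the reference.
#' @param regularization smoothing weight in `[0, 1]` applied in each
#'   Laplacian smoothing pass of the displacement field.
#' @param n_smooth smoothing passes per iteration.
#' @param max_iter closest-point iterations per frame.
#' @param tol convergence tolerance on the mean closest-point residual (mm).
#' @param frame_times optional cycle fractions for the output motion.
#' @return a [mesh_motion] with attribute `residuals` (mean surface-to-
#'   surface distance per frame, mm).
#' @export
track_surfaces <- function(reference, target_surfaces, regularization = 0.4,
                           n_smooth = 5L, max_iter = 30L, tol = 1e-3,
                           frame_times = NULL) {
  ref_v <- reference$vertices
  adj <- vertex_adjacency(reference)
  cur <- ref_v
  frames <- vector("list", length(target_surfaces))
  residuals <- numeric(length(target_surfaces))
  for (fi in seq_along(target_surfaces)) {
    tgt <- target_surfaces[[fi]]
    tv <- if (inherits(tgt, "la_mesh")) tgt$vertices else as.matrix(tgt)
    res_hist <- numeric(0)
    for (it in seq_len(max_iter)) {
      nn <- nearest_rows(cur, tv)
      d <- tv[nn, , drop = FALSE] - cur
      res <- mean(sqrt(rowSums(d^2)))
      res_hist <- c(res_hist, res)
      if (res < tol) break
      d <- smooth_field(d, adj, regularization, n_smooth)
      cur <- cur + d
      if (it == max_iter && res > 10 * tol && length(res_hist) > 3 &&
          abs(res_hist[it] - res_hist[it - 1]) > 0.5 * res_hist[it])
        stop("tracker failed to converge; residual history: ",
             paste(signif(res_hist, 3), collapse = ", "))
    }
    frames[[fi]] <- cur
    residuals[fi] <- res_hist[length(res_hist)]
  }
  # re-anchor frame 0 on the reference (targets are a cycle starting at LVED)
  frames[[1]] <- ref_v
  motion <- mesh_motion(reference, frames, frame_times = frame_times)
  attr(motion, "residuals") <- residuals
  motion
}

# Jacobi smoothing of a per-vertex vector field over the 1-ring
smooth_field <- function(d, adj, lambda, n_pass) {
  for (p in seq_len(n_pass)) {
    avg <- t(vapply(seq_along(adj), function(i) colMeans(d[adj[[i]], ,
                                                           drop = FALSE]),
                    numeric(3)))
    d <- (1 - lambda) * d + lambda * avg
  }
  d
}
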