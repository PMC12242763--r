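#' Fibrosis quantification configuration
#'
#' @param iir_threshold image-intensity-ratio threshold defining enhancement
#'   (default 1.2).
#' @param stage_bounds strictly increasing percent-area cut points for the
#'   four fibrosis stages (default 10, 20, 30).
#' @param projection_depth normal projection depth in mm for image-to-surface
#'   sampling (default 3).
#' @param triangle_rule how a triangle's enhancement is decided:
#'   `"triangle_mean"` (mean of its three vertex IIRs exceeds the threshold,
#'   the default) or `"vertex_area"` (each vertex contributes a third of the
#'   triangle area).
#' @return list of class `fibrosis_config`.
#' @export
fibrosis_config <- function(iir_threshold = 1.2, stage_bounds = c(10, 20, 30),
                            projection_depth = 3,
                            triangle_rule = c("triangle_mean", "vertex_area")) {
  if (iir_threshold <= 0) stop("iir_threshold must be > 0")
  if (length(stage_bounds) != 3L || is.unsorted(stage_bounds, strictly = TRUE))
    stop("stage_bounds must be three strictly increasing cut points")
  structure(list(iir_threshold = iir_threshold, stage_bounds = stage_bounds,
                 projection_depth = projection_depth,
                 triangle_rule = match.arg(triangle_rule)),
            class = "fibrosis_config")
}

#' Image intensity ratio
#'
#' Elementwise ratio of wall intensity to the mean blood-pool intensity;
#' values above the configured threshold (1.2 by default) mark enhancement.
#'
#' @param vertex_intensity numeric per-vertex intensities.
#' @param blood_pool_mean mean blood-pool intensity (> 0).
#' @return numeric per-vertex ratios.
#' @export
compute_iir <- function(vertex_intensity, blood_pool_mean) {
  if (!is.numeric(blood_pool_mean) || length(blood_pool_mean) != 1L ||
      blood_pool_mean <= 0)
    stop("blood_pool_mean must be a single positive number")
  as.numeric(vertex_intensity) / blood_pool_mean
}

#' Fibrosis stage from percent area of enhancement
#'
#' Stages follow half-open intervals `[0,10) -> 1`, `[10,20) -> 2`,
#' `[20,30) -> 3`; severe fibrosis (stage 4) requires strictly more than
#' 30% enhanced area, so exactly 30.0 is stage 3.
#'
#' @param enhancement_pct percent of regional area enhanced, in `[0, 100]`.
#' @param config a [fibrosis_config].
#' @return list with integer `stage` (1--4) and logical `severe`
#'   (vectorized over `enhancement_pct`).
#' @export
stage_enhancement <- function(enhancement_pct, config = fibrosis_config()) {
  p <- as.numeric(enhancement_pct)
  if (any(p < 0 | p > 100 | !is.finite(p)))
    stop("enhancement_pct must lie in [0, 100]")
  b <- config$stage_bounds
  stage <- ifelse(p > b[3], 4L, ifelse(p >= b[2], 3L, ifelse(p >= b[1], 2L, 1L)))
  list(stage = as.integer(stage), severe = p > b[3])
}

#' Regional enhancement, stage and severe-fibrosis flags
#'
#' For each region, `enhancement_pct` is 100 times the summed area of
#' enhanced triangles over the regional total area. Under the default
#' triangle rule a triangle is enhanced when the mean of its three vertex
#' IIRs exceeds the threshold; under `"vertex_area"` each above-threshold
#' vertex contributes a third of the triangle's area.
#'
#' @param iir per-vertex intensity ratios from [compute_iir].
#' @param regions vertex region factor from [assign_regions].
#' @param mesh the [la_mesh] the fields live on.
#' @param config a [fibrosis_config].
#' @return data.frame of class `fibrosis_map` with columns `region`,
#'   `enhancement_pct`, `stage`, `severe`, plus attribute `whole_surface_pct`.
#' @export
regional_enhancement <- function(iir, regions, mesh,
                                 config = fibrosis_config()) {
  treg <- triangle_regions(mesh, regions)
  a <- triangle_areas(mesh)
  tri <- mesh$triangles
  iir_tri <- matrix(iir[tri], ncol = 3)
  if (config$triangle_rule == "triangle_mean") {
    enh_area <- a * (rowMeans(iir_tri) > config$iir_threshold)
  } else {
    enh_area <- a * rowMeans(iir_tri > config$iir_threshold)
  }
  lev <- la_regions()
  out <- data.frame(region = factor(lev, levels = lev),
                    enhancement_pct = NA_real_)
  for (i in seq_along(lev)) {
    sel <- which(treg == lev[i])
    if (!length(sel)) stop("empty region: ", lev[i])
    out$enhancement_pct[i] <- 100 * sum(enh_area[sel]) / sum(a[sel])
  }
  st <- stage_enhancement(out$enhancement_pct, config)
  out$stage <- st$stage
  out$severe <- st$severe
  body <- !is.na(treg)
  attr(out, "whole_surface_pct") <- 100 * sum(enh_area[body]) / sum(a[body])
  class(out) <- c("fibrosis_map", "data.frame")
  out
}

#' Project a 3D intensity image onto a surface mesh
#'
#' Samples the image by trilinear interpolation along the outward vertex
#' normal over `[-depth, +depth]` and keeps the maximum (bright-rim
#' capture). With `depth = 0` only the vertex position is sampled.
#'
#' @param image a [la_image] (see [voxelize_intensity]) or RNifti image with
#'   a diagonal world transform.
#' @param mesh an [la_mesh] in the image's physical coordinate frame.
#' @param depth projection depth in mm.
#' @param step sampling step along the normal in mm (default half the
#'   smallest voxel dimension).
#' @return numeric per-vertex intensities.
#' @export
project_image_to_surface <- function(image, mesh, depth = 3, step = NULL) {
  img <- as_la_image(image)
  if (is.null(step)) step <- min(img$spacing) / 2
  offs <- if (depth > 0) seq(-depth, depth, by = step) else 0
  nrm <- vertex_normals(mesh)
  v <- mesh$vertices
  out <- rep(-Inf, nrow(v))
  any_inside <- rep(FALSE, nrow(v))
  for (o in offs) {
    p <- v + o * nrm
    s <- trilinear_sample(img, p)
    inside <- !is.na(s)
    any_inside <- any_inside | inside
    out[inside] <- pmax(out[inside], s[inside])
  }
  if (!all(any_inside))
    stop("vertex ", which(!any_inside)[1],
         " samples entirely outside image bounds")
  out
}

#' Estimate the mean blood-pool intensity from the chamber cavity
#'
#' Draws sample points inside the chamber by shrinking surface points
#' towards the cavity centroid, discards samples closer than
#' `projection_depth` to the wall, and averages the image there.
#'
#' @param image a [la_image] or RNifti image.
#' @param mesh an [la_mesh] delimiting the cavity.
#' @param config a [fibrosis_config] (for `projection_depth`).
#' @param n_samples number of interior sample points.
#' @param seed RNG seed for the sample positions.
#' @return estimated mean blood-pool intensity.
#' @export
estimate_blood_pool_mean <- function(image, mesh, config = fibrosis_config(),
                                     n_samples = 2000L, seed = 1L) {
  img <- as_la_image(image)
  body <- which(mesh$labels %in% c("body", "mitral_rim"))
  ctr <- colMeans(mesh$vertices[body, , drop = FALSE])
  rs <- withr_seed(seed, {
    idx <- sample(body, n_samples, replace = TRUE)
    frac <- stats::runif(n_samples)^(1 / 3) * 0.95
    list(idx = idx, frac = frac)
  })
  p <- sweep(sweep(mesh$vertices[rs$idx, , drop = FALSE], 2, ctr, "-") *
               rs$frac, 2, ctr, "+")
  nn <- nearest_rows(p, mesh$vertices)
  dwall <- sqrt(rowSums((p - mesh$vertices[nn, , drop = FALSE])^2))
  keep <- dwall > config$projection_depth
  if (!any(keep)) stop("no cavity samples remain after wall erosion")
  s <- trilinear_sample(img, p[keep, , drop = FALSE])
  mean(s, na.rm = TRUE)
}

# evaluate block with a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

#' Simple axis-aligned 3D intensity image
#'
#' @param data 3D numeric array.
#' @param spacing voxel size (mm), length 3.
#' @param origin world position of voxel (1,1,1), length 3.
#' @return object of class `la_image`.
#' @export
la_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L,
            length(origin) == 3L, all(spacing > 0))
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)), class = "la_image")
}

as_la_image <- function(image) {
  if (inherits(image, "la_image")) return(image)
  if (inherits(image, "niftiImage") || !is.null(attr(image, "pixdim"))) {
    arr <- as.array(image)
    # recover spacing/origin from the (axis-aligned) world transform
    xf <- RNifti::xform(image)
    sp <- abs(c(xf[1, 1], xf[2, 2], xf[3, 3]))
    origin <- xf[1:3, 4]
    return(la_image(arr, spacing = sp, origin = origin))
  }
  if (is.array(image) && length(dim(image)) == 3L) return(la_image(image))
  stop("unsupported image type")
}

#' Write an intensity image as NIfTI
#' @param image a [la_image].
#' @param path output `.nii` path (written uncompressed).
#' @return `path`, invisibly.
#' @export
write_la_image <- function(image, path) {
  im <- RNifti::asNifti(image$data)
  xf <- diag(4)
  diag(xf)[1:3] <- image$spacing
  xf[1:3, 4] <- image$origin
  im <- RNifti::`sform<-`(im, structure(xf, code = 2L))
  RNifti::writeNifti(im, path, compression = 0)
  invisible(path)
}

#' Read a NIfTI intensity image
#' @param path a `.nii`/`.nii.gz` file with axis-aligned transform.
#' @return a [la_image].
#' @export
read_la_image <- function(path) {
  as_la_image(RNifti::readNifti(path))
}

# trilinear interpolation at world points; NA outside bounds
trilinear_sample <- function(img, p) {
  d <- dim(img$data)
  g <- sweep(sweep(p, 2, img$origin, "-"), 2, img$spacing, "/") + 1  # 1-based
  i0 <- floor(g)
  fr <- g - i0
  ok <- i0[, 1] >= 1 & i0[, 1] < d[1] & i0[, 2] >= 1 & i0[, 2] < d[2] &
    i0[, 3] >= 1 & i0[, 3] < d[3]
  out <- rep(NA_real_, nrow(p))
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]; fx <- fr[ok, , drop = FALSE]
  at <- function(dx, dy, dz)
    img$data[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  v <- at(0, 0, 0) * (1 - fx[, 1]) * (1 - fx[, 2]) * (1 - fx[, 3]) +
    at(1, 0, 0) * fx[, 1] * (1 - fx[, 2]) * (1 - fx[, 3]) +
    at(0, 1, 0) * (1 - fx[, 1]) * fx[, 2] * (1 - fx[, 3]) +
    at(0, 0, 1) * (1 - fx[, 1]) * (1 - fx[, 2]) * fx[, 3] +
    at(1, 1, 0) * fx[, 1] * fx[, 2] * (1 - fx[, 3]) +
    at(1, 0, 1) * fx[, 1] * (1 - fx[, 2]) * fx[, 3] +
    at(0, 1, 1) * (1 - fx[, 1]) * fx[, 2] * fx[, 3] +
    at(1, 1, 1) * fx[, 1] * fx[, 2] * fx[, 3]
  out[ok] <- v
  out
}
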