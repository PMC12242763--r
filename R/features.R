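#' Reservoir strain of a curve
#'
#' The amplitude of the strain curve over the cycle: `max - min`.
#'
#' @param curve numeric strain curve (%), at least 3 frames.
#' @return reservoir strain in percent.
#' @export
reservoir_strain <- function(curve) {
  if (length(curve) < 3L) stop("curve must have at least 3 frames")
  max(curve) - min(curve)
}

#' Peak strain rate of a cyclic curve
#'
#' Maximum absolute central-difference derivative with respect to cycle
#' fraction. With `periodic = TRUE` (the default, appropriate for closed
#' strain curves) the ends wrap around the cycle; with `periodic = FALSE`
#' one-sided differences are used at the ends.
#'
#' @param curve numeric samples (%).
#' @param frame_times cycle fractions in `[0, 1)`; uniform grid by default.
#' @param periodic wrap the cycle ends?
#' @return peak rate in percent per cycle.
#' @export
peak_strain_rate <- function(curve, frame_times = NULL, periodic = TRUE) {
  n <- length(curve)
  if (n < 3L) stop("curve must have at least 3 frames")
  if (is.null(frame_times)) frame_times <- (seq_len(n) - 1) / n
  if (anyDuplicated(frame_times)) stop("duplicate frame times")
  if (periodic) {
    y <- c(curve[n], curve, curve[1])
    t <- c(frame_times[n] - 1, frame_times, frame_times[1] + 1)
    dr <- (y[3:(n + 2)] - y[1:n]) / (t[3:(n + 2)] - t[1:n])
  } else {
    dr <- numeric(n)
    dr[2:(n - 1)] <- (curve[3:n] - curve[1:(n - 2)]) /
      (frame_times[3:n] - frame_times[1:(n - 2)])
    dr[1] <- (curve[2] - curve[1]) / (frame_times[2] - frame_times[1])
    dr[n] <- (curve[n] - curve[n - 1]) / (frame_times[n] - frame_times[n - 1])
  }
  max(abs(dr))
}

#' Fit a PCA basis to strain curves
#'
#' Mean-centred orthonormal components of resampled strain curves, ordered
#' by explained variance. Intended to be fitted on training curves only and
#' applied to new curves via [project_strain_pca].
#'
#' @param curves matrix, one curve per row, common frame grid.
#' @return list of class `strain_pca`: `mean`, `loadings` (columns are
#'   components), `sdev`, `var_explained`.
#' @export
fit_strain_pca <- function(curves) {
  curves <- as.matrix(curves)
  if (nrow(curves) < 2L) stop("need at least 2 curves")
  if (all(abs(sweep(curves, 2, curves[1, ])) < 1e-12))
    stop("curves are identical; PCA input has rank 0")
  p <- stats::prcomp(curves, center = TRUE, scale. = FALSE)
  structure(list(mean = p$center, loadings = p$rotation, sdev = p$sdev,
                 var_explained = p$sdev^2 / sum(p$sdev^2)),
            class = "strain_pca")
}

#' Project curves onto a fitted PCA basis
#' @param fit a [fit_strain_pca] result.
#' @param curves matrix of curves on the same grid (or a single curve).
#' @param n_comp number of component scores to return.
#' @return matrix of scores (rows = curves).
#' @export
project_strain_pca <- function(fit, curves, n_comp = 2L) {
  if (is.null(dim(curves))) curves <- matrix(curves, nrow = 1)
  n_comp <- min(n_comp, ncol(fit$loadings))
  sweep(as.matrix(curves), 2, fit$mean) %*% fit$loadings[, seq_len(n_comp),
                                                         drop = FALSE]
}

#' Healthy-cohort normalization parameters
#'
#' Per-region mean and SD of regional reservoir strain in a reference
#' (healthy) cohort, used to express patient strains as Z-scores.
#'
#' @param features data.frame with columns `region` and `rs`.
#' @return data.frame of class `cohort_normalization` with `region`,
#'   `mu_healthy`, `sd_healthy`.
#' @export
cohort_normalization <- function(features) {
  sp <- split(features$rs, features$region)
  out <- data.frame(region = factor(names(sp), levels = la_regions()),
                    mu_healthy = vapply(sp, mean, numeric(1)),
                    sd_healthy = vapply(sp, stats::sd, numeric(1)))
  if (any(!is.finite(out$sd_healthy)) || any(out$sd_healthy <= 0))
    stop("sd_healthy must be > 0 in every region")
  class(out) <- c("cohort_normalization", "data.frame")
  rownames(out) <- NULL
  out
}

#' Z-score a strain value against healthy-cohort parameters
#'
#' `z = (x - mu_healthy) / sd_healthy` with the matching region's
#' parameters.
#'
#' @param x strain value(s) in percent.
#' @param norm a [cohort_normalization].
#' @param region region name(s), recycled against `x`.
#' @return numeric z-score(s).
#' @export
zscore <- function(x, norm, region) {
  i <- match(as.character(region), as.character(norm$region))
  if (any(is.na(i))) stop("region missing from normalization: ",
                          paste(unique(region[is.na(i)]), collapse = ", "))
  (x - norm$mu_healthy[i]) / norm$sd_healthy[i]
}

#' Extract strain/fibrosis features from one subject
#'
#' Runs the measurement pipeline (area strain, regional curves, volume
#' curve, IIR fibrosis map) on a subject's corresponded motion and
#' intensity field.
#'
#' @param subject an `la_subject` (or compatible list).
#' @param n_frames common resampling grid size (default 30).
#' @param config a [fibrosis_config].
#' @param motion optional replacement motion (e.g. from [track_surfaces]).
#' @return list with `features` (6-row data.frame), `curves` (6 x
#'   `n_frames` matrix), `map` (a `fibrosis_map`).
#' @export
analyze_subject <- function(subject, n_frames = 30L,
                            config = fibrosis_config(), motion = NULL) {
  if (is.null(motion)) motion <- subject$motion
  es <- area_strain(motion)
  sc <- regional_strain_curves(es, subject$regions, motion)
  lev <- la_regions()
  curves <- t(vapply(lev, function(r)
    resample_curve(sc$regional[r, ], sc$frame_times, n_frames),
    numeric(n_frames)))
  vc <- volume_curve(motion)
  iir <- compute_iir(subject$vertex_intensity, subject$blood_pool_mean)
  map <- regional_enhancement(iir, subject$regions, subject$anatomy, config)
  gcurve <- resample_curve(sc$global, sc$frame_times, n_frames)
  feats <- data.frame(
    subject = subject$id, cohort = subject$cohort,
    region = factor(lev, levels = lev),
    rs = apply(curves, 1, reservoir_strain),
    srate = apply(curves, 1, peak_strain_rate),
    global_rs = reservoir_strain(gcurve),
    lav = vc$lav_max, laef = vc$laef,
    enhancement_pct = map$enhancement_pct,
    stage = map$stage, severe = map$severe)
  list(features = feats, curves = curves, map = map, volume = vc)
}

#' Analyze a whole cohort
#'
#' @param cohort an `la_cohort`.
#' @param n_frames common curve grid (default 30).
#' @param config a [fibrosis_config].
#' @param progress print a dot per subject.
#' @return list with `features` (6 rows per subject), `curves` (aligned
#'   matrix), `maps` (per-subject `fibrosis_map`s).
#' @export
analyze_cohort <- function(cohort, n_frames = 30L,
                           config = fibrosis_config(), progress = FALSE) {
  res <- lapply(cohort$subjects, function(s) {
    if (progress) cat(".")
    analyze_subject(s, n_frames, config)
  })
  if (progress) cat("\n")
  features <- do.call(rbind, lapply(res, `[[`, "features"))
  curves <- do.call(rbind, lapply(res, `[[`, "curves"))
  rownames(curves) <- NULL
  maps <- lapply(res, `[[`, "map")
  names(maps) <- vapply(cohort$subjects, `[[`, character(1), "id")
  list(features = features, curves = curves, maps = maps)
}

#' Build the classification feature table
#'
#' One row per (subject, region): regional features (region, regional area
#' RS, peak strain rate, PC scores of the resampled curves), global features
#' (global area RS, LAV, LAEF), Z-scored regional RS when a healthy
#' normalization is supplied, and the severe-fibrosis label. The raw curves
#' ride along as attribute `curves` so cross-validation can refit the PCA on
#' training folds only; the `pc1`/`pc2` columns here are full-data scores
#' for exploration.
#'
#' @param analysis result of [analyze_cohort].
#' @param normalization optional [cohort_normalization] from a healthy
#'   cohort.
#' @param pca_pool `"all"` (one basis for all curves, default) or
#'   `"by_region"`.
#' @return data.frame of class `feature_table` with attribute `curves`.
#' @export
build_feature_table <- function(analysis, normalization = NULL,
                                pca_pool = c("all", "by_region")) {
  pca_pool <- match.arg(pca_pool)
  ft <- analysis$features
  curves <- analysis$curves
  if (nrow(ft) != nrow(curves)) stop("features and curves misaligned")
  miss <- !stats::complete.cases(ft[, c("subject", "region", "rs", "severe")])
  if (any(miss))
    stop("missing subject-region rows: ",
         paste(ft$subject[miss], ft$region[miss], collapse = ", "))
  sc <- pca_scores(curves, ft$region, pca_pool)
  ft$pc1 <- sc[, 1]
  ft$pc2 <- sc[, 2]
  if (!is.null(normalization))
    ft$z_rs <- zscore(ft$rs, normalization, ft$region)
  attr(ft, "curves") <- curves
  attr(ft, "pca_pool") <- pca_pool
  class(ft) <- c("feature_table", "data.frame")
  ft
}

pca_scores <- function(curves, region, pca_pool, train_idx = NULL) {
  n <- nrow(curves)
  if (is.null(train_idx)) train_idx <- seq_len(n)
  out <- matrix(NA_real_, n, 2)
  if (pca_pool == "all") {
    fit <- fit_strain_pca(curves[train_idx, , drop = FALSE])
    out <- project_strain_pca(fit, curves, 2)
  } else {
    for (r in la_regions()) {
      tr <- intersect(train_idx, which(region == r))
      sel <- which(region == r)
      fit <- fit_strain_pca(curves[tr, , drop = FALSE])
      out[sel, ] <- project_strain_pca(fit, curves[sel, , drop = FALSE], 2)
    }
  }
  out
}
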