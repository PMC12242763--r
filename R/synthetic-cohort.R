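#' Generate one synthetic subject
#'
#' Draws the subject-level targets (LAV, LAEF, per-region reservoir
#' strains), builds the labelled anatomy at the implied minimum volume,
#' parameterizes and parcellates it, generates the cyclic motion and the
#' LGE-like intensity field, and returns everything together with the
#' construction ground truth.
#'
#' @param spec a [cohort_spec].
#' @param subject_seed integer seed; all randomness derives from it.
#' @param subject_id identifier stored in the result.
#' @return object of class `la_subject`: list with `anatomy`, `uac`,
#'   `regions`, `motion`, `vertex_intensity`, `blood_pool_mean`, `truth`
#'   (targets, measured strain curves and volumes, regional fibrosis table).
#' @export
generate_subject <- function(spec, subject_seed = 1L, subject_id = "S001") {
  pre <- generate_subject_pre(spec, subject_seed, subject_id)
  finalize_subject(pre, spec, subject_seed)
}

# anatomy + parameterization + motion; fibrosis is added by
# finalize_subject so cohort generation can standardize the link covariates
# empirically across subjects first
generate_subject_pre <- function(spec, subject_seed, subject_id) {
  set.seed(derive_seed(subject_seed, 0L))
  lav <- rtruncnorm(1, spec$lav_mean, spec$lav_sd,
                    spec$lav_range[1], spec$lav_range[2])
  rs_targets <- draw_rs_targets(spec)
  anatomy <- generate_anatomy(spec, derive_seed(subject_seed, 1L),
                              volume_target = lav * (1 - spec$laef_mean / 100))
  uac <- build_uac(anatomy)
  regions <- assign_regions(anatomy, uac, spec$antra_radius)
  motion <- generate_motion(anatomy, spec, derive_seed(subject_seed, 2L),
                            regions = regions, rs_targets = rs_targets)
  truth <- attr(motion, "truth")
  truth$lav_target <- lav
  list(id = subject_id, cohort = spec$cohort, anatomy = anatomy, uac = uac,
       regions = regions, motion = motion, truth = truth,
       rs_targets = rs_targets, lav_drawn = lav)
}

# link on the drawn anatomical size (strain-independent by construction)
# and the emergent emptying fraction; link_refs overrides the spec's
# standardization references (used for cohort-empirical standardization)
finalize_subject <- function(pre, spec, subject_seed, link_refs = NULL) {
  lspec <- spec
  if (!is.null(link_refs)) lspec[names(link_refs)] <- link_refs
  fib <- generate_fibrosis(pre$anatomy, pre$regions,
                           list(lav = pre$lav_drawn,
                                laef = pre$truth$volume$laef),
                           lspec, derive_seed(subject_seed, 3L),
                           rs_targets = pre$rs_targets)
  truth <- pre$truth
  truth$fibrosis <- fib$truth
  structure(list(id = pre$id, cohort = pre$cohort,
                 anatomy = pre$anatomy, uac = pre$uac, regions = pre$regions,
                 motion = pre$motion, vertex_intensity = fib$vertex_intensity,
                 blood_pool_mean = fib$blood_pool_mean, truth = truth),
            class = "la_subject")
}

#' @export
print.la_subject <- function(x, ...) {
  cat("<la_subject> ", x$id, " (", x$cohort, "): LAV ",
      round(x$truth$volume$lav_max, 1), " mL, LAEF ",
      round(x$truth$volume$laef, 1), "%, ",
      sum(x$truth$fibrosis$severe), "/6 severe regions\n", sep = "")
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Fully seeded: the same spec yields bitwise-identical subjects. The truth
#' table has one row per (subject, region), 6 rows per subject.
#'
#' @param spec a [cohort_spec].
#' @param progress print a dot per subject.
#' @return object of class `la_cohort`: list with `subjects` (list of
#'   [generate_subject] results), `table` (truth data.frame), `spec`.
#' @export
generate_cohort <- function(spec, progress = FALSE) {
  set.seed(spec$seed)
  seeds <- sample.int(2147483000L, spec$n_subjects)
  pres <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    id <- sprintf("%s%03d", toupper(substr(spec$cohort, 1, 1)), i)
    pres[[i]] <- generate_subject_pre(spec, seeds[i], id)
    if (progress) cat(".")
  }
  # standardize the link covariates against the realized cohort so the
  # severe-fibrosis marginals match the configured prevalences
  lavs <- vapply(pres, `[[`, numeric(1), "lav_drawn")
  laefs <- vapply(pres, function(p) p$truth$volume$laef, numeric(1))
  link_refs <- if (spec$n_subjects >= 8) {
    list(lav_mean = mean(lavs), lav_sd = max(stats::sd(lavs), 1e-6),
         laef_mean = mean(laefs), laef_sd = max(stats::sd(laefs), 1e-6))
  } else NULL
  subjects <- vector("list", spec$n_subjects)
  rows <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    s <- finalize_subject(pres[[i]], spec, seeds[i], link_refs)
    subjects[[i]] <- s
    rows[[i]] <- data.frame(
      subject = s$id, cohort = spec$cohort,
      region = s$truth$fibrosis$region,
      rs_true = as.numeric(s$truth$rs[as.character(s$truth$fibrosis$region)]),
      enhancement_pct = s$truth$fibrosis$enhancement_pct,
      stage = s$truth$fibrosis$stage,
      severe = s$truth$fibrosis$severe,
      lav = s$truth$volume$lav_max,
      laef = s$truth$volume$laef,
      global_rs_true = s$truth$global_rs)
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  structure(list(subjects = subjects, table = do.call(rbind, rows),
                 spec = spec),
            class = "la_cohort")
}

#' @export
print.la_cohort <- function(x, ...) {
  tb <- x$table
  cat("<la_cohort> ", x$spec$cohort, ", n = ", length(x$subjects),
      " subjects (", nrow(tb), " region rows)\n", sep = "")
  cat("  pooled RS ", round(mean(tb$rs_true), 1), " +/- ",
      round(stats::sd(tb$rs_true), 1), " %; severe regions ",
      round(100 * mean(tb$severe), 1), "%\n", sep = "")
  invisible(x)
}

#' Write a cohort to disk
#'
#' Per subject: anatomy VTK (with intensity, IIR-ready fields and regions as
#' point data), the motion frame series, and a JSON truth record; plus the
#' cohort truth table CSV, a spec echo JSON, and a manifest with file
#' hashes.
#'
#' @param cohort an [la_cohort].
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (s in cohort$subjects) {
    sd <- file.path(dir, s$id)
    dir.create(sd, showWarnings = FALSE)
    f1 <- file.path(sd, "anatomy.vtk")
    write_vtk(s$anatomy, f1,
              point_data = list(intensity = s$vertex_intensity,
                                region = as.integer(s$regions),
                                uac_alpha = s$uac$alpha,
                                uac_beta = s$uac$beta))
    write_motion(s$motion, sd)
    f2 <- file.path(sd, "truth.json")
    jsonlite::write_json(
      list(id = s$id, cohort = s$cohort,
           blood_pool_mean = s$blood_pool_mean,
           lav = s$truth$volume$lav, laef = s$truth$volume$laef,
           rs = as.list(s$truth$rs),
           fibrosis = s$truth$fibrosis),
      f2, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    files <- c(files, f1, f2)
  }
  tab <- file.path(dir, "truth_table.csv")
  utils::write.csv(cohort$table, tab, row.names = FALSE)
  spec_path <- file.path(dir, "spec.json")
  jsonlite::write_json(unclass(cohort$spec), spec_path, auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, tab, spec_path)
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(seed = cohort$spec$seed, n_subjects = cohort$spec$n_subjects,
         files = basename(files),
         md5 = unname(tools::md5sum(files))),
    manifest, auto_unbox = TRUE)
  invisible(manifest)
}

#' Voxelize a subject's intensity field into a 3D image
#'
#' Builds an axis-aligned image whose near-wall voxels carry the nearest
#' vertex's intensity, cavity voxels carry blood-pool intensities, and
#' exterior voxels a dark background.
#'
#' @param subject an `la_subject` (or a list with `anatomy`,
#'   `vertex_intensity`, `blood_pool_mean`).
#' @param voxel_size isotropic voxel size in mm.
#' @param wall_thickness half-thickness of the painted wall band in mm
#'   (default `max(1.5, 0.75 * voxel_size)`).
#' @param margin bounding-box padding in mm.
#' @param noise_sd additive Gaussian image noise (absolute units).
#' @param seed RNG seed for the noise.
#' @return a [la_image].
#' @export
voxelize_intensity <- function(subject, voxel_size = 1.5,
                               wall_thickness = NULL, margin = 6,
                               noise_sd = 0, seed = 1L) {
  if (voxel_size <= 0) stop("voxel_size must be > 0")
  if (voxel_size > 3)
    warning("voxel_size exceeds the wall-feature scale; projection will be lossy")
  if (is.null(wall_thickness)) wall_thickness <- max(1.5, 0.75 * voxel_size)
  mesh <- subject$anatomy
  v <- mesh$vertices
  lo <- apply(v, 2, min) - margin
  hi <- apply(v, 2, max) + margin
  dims <- pmax(ceiling((hi - lo) / voxel_size), 4L)
  ax <- lapply(1:3, function(k) lo[k] + (seq_len(dims[k]) - 0.5) * voxel_size)
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  nn <- nearest_rows(pts, v)
  dwall <- sqrt(rowSums((pts - v[nn, , drop = FALSE])^2))
  body <- which(mesh$labels %in% c("body", "mitral_rim"))
  ctr <- colMeans(v[body, , drop = FALSE])
  rp <- sqrt(rowSums(sweep(pts, 2, ctr, "-")^2))
  rs <- sqrt(rowSums(sweep(v[nn, , drop = FALSE], 2, ctr, "-")^2))
  bg <- 0.3 * subject$blood_pool_mean
  val <- rep(bg, nrow(pts))
  inside <- rp < rs & dwall > wall_thickness
  val[inside] <- subject$blood_pool_mean
  wall <- dwall <= wall_thickness
  val[wall] <- subject$vertex_intensity[nn[wall]]
  if (noise_sd > 0) {
    set.seed(seed)
    val <- val + stats::rnorm(length(val), 0, noise_sd)
  }
  la_image(array(val, dim = dims), spacing = rep(voxel_size, 3), origin =
             lo + 0.5 * voxel_size)
}
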