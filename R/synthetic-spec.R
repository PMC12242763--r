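#' Synthetic cohort specification
#'
#' Defines the statistical structure of a generated atrial cohort: cohort
#' strain level (pooled regional reservoir-strain mean/SD with a fixed
#' regional pattern), chamber size and emptying fraction, per-region
#' fibrosis burden distributions, and the link model tying severe regional
#' fibrosis to standardized LAV, LAEF and region (with strain decoupled
#' unless `strain_fibrosis_coupling` is nonzero).
#'
#' Cohort presets: `healthy` pooled RS 48.0 +/- 33.2 % with low fibrosis;
#' `AF` pooled RS 19.5 +/- 15.7 %, region burden means lateral 44.4,
#' posterior 40.9, septal 32.7, anterior 31.4, LPVA 26.0 (RPVA 28.7,
#' between LPVA and anterior), severe-fibrosis prevalence highest in the
#' lateral then posterior walls; `DCM` intermediate. Any field can be
#' overridden.
#'
#' The emptying fraction is emergent: once the area-strain level is fixed,
#' a closed surface's peak volume is bounded by the volume of the sphere
#' with the peak surface area, so LAEF follows the strain pattern rather
#' than being a free dial. `laef_mean`/`laef_sd` are therefore
#' standardization references for the emergent distribution (used by the
#' severe-fibrosis link model), not targets; the cohort ordering
#' (healthy > DCM > AF) is preserved. See the methods vignette.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param cohort one of `"healthy"`, `"AF"`, `"DCM"`.
#' @param seed integer RNG seed for the whole cohort.
#' @param frames_per_cycle frames per cardiac cycle (default 30, >= 3).
#' @param ... named overrides of any preset field (see Details).
#' @return list of class `cohort_spec`.
#' @details Overridable fields include `rs_mean`, `rs_sd`,
#'   `rs_region_dev` (named per-region offsets summing to 0),
#'   `rs_subject_sd`, `rs_floor`, `lav_mean`, `lav_sd`, `lav_range`,
#'   `laef_mean`, `laef_sd`, `fibrosis_region_mu` / `fibrosis_region_sd`
#'   (named, percent), `severe_prevalence` (named, 0--1), `link_lav`,
#'   `link_laef`, `strain_fibrosis_coupling`, `blood_pool_mean`,
#'   `intensity_noise_sd` (relative), `motion_jitter_sd` (mm),
#'   `mesh_subdiv`, `antra_radius`.
#' @export
cohort_spec <- function(n_subjects, cohort = c("AF", "healthy", "DCM"),
                        seed = 1L, frames_per_cycle = 30L, ...) {
  cohort <- match.arg(cohort)
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  if (frames_per_cycle < 3L) stop("frames_per_cycle must be >= 3")
  reg <- la_regions()
  base <- switch(cohort,
    healthy = list(
      rs_mean = 48.0, rs_sd = 33.2,
      rs_region_dev = c(LPVA = -6, RPVA = -8, posterior = -4, septal = 18,
                        anterior = 5, lateral = -5),
      rs_subject_sd = 12,
      lav_mean = 70, lav_sd = 14, lav_range = c(35, 140),
      laef_mean = 34, laef_sd = 11,
      fibrosis_region_mu = c(LPVA = 6, RPVA = 7, posterior = 9.5, septal = 8,
                             anterior = 8, lateral = 10),
      fibrosis_region_sd = c(LPVA = 5, RPVA = 5, posterior = 5, septal = 5,
                             anterior = 5, lateral = 5),
      severe_prevalence = c(LPVA = 0.02, RPVA = 0.02, posterior = 0.03,
                            septal = 0.02, anterior = 0.02, lateral = 0.03)),
    AF = list(
      rs_mean = 19.5, rs_sd = 15.7,
      rs_region_dev = c(LPVA = -3.5, RPVA = -1, posterior = -2, septal = 7,
                        anterior = 2, lateral = -2.5),
      rs_subject_sd = 6,
      lav_mean = 115, lav_sd = 28, lav_range = c(55, 220),
      laef_mean = 19, laef_sd = 7,
      fibrosis_region_mu = c(LPVA = 26.0, RPVA = 28.7, posterior = 40.9,
                             septal = 32.7, anterior = 31.4, lateral = 44.4),
      fibrosis_region_sd = c(LPVA = 18.5, RPVA = 17.0, posterior = 21.8,
                             septal = 20.1, anterior = 14.9, lateral = 17.2),
      severe_prevalence = c(LPVA = 0.45, RPVA = 0.55, posterior = 0.66,
                            septal = 0.60, anterior = 0.55, lateral = 0.851)),
    DCM = list(
      rs_mean = 35, rs_sd = 25,
      rs_region_dev = c(LPVA = -4, RPVA = -4, posterior = -3, septal = 12,
                        anterior = 3, lateral = -4),
      rs_subject_sd = 9,
      lav_mean = 95, lav_sd = 25, lav_range = c(45, 190),
      laef_mean = 27, laef_sd = 9,
      fibrosis_region_mu = c(LPVA = 18, RPVA = 20, posterior = 28, septal = 24,
                             anterior = 23, lateral = 30),
      fibrosis_region_sd = c(LPVA = 14, RPVA = 14, posterior = 16, septal = 15,
                             anterior = 14, lateral = 15),
      severe_prevalence = c(LPVA = 0.14, RPVA = 0.18, posterior = 0.28,
                            septal = 0.22, anterior = 0.20, lateral = 0.35)))
  spec <- c(list(n_subjects = as.integer(n_subjects), cohort = cohort,
                 seed = as.integer(seed),
                 frames_per_cycle = as.integer(frames_per_cycle)),
            base,
            list(rs_floor = 1,
                 link_lav = 2.0, link_laef = -0.5,
                 strain_fibrosis_coupling = 0,
                 blood_pool_mean = 100,
                 intensity_noise_sd = 0.02,
                 motion_jitter_sd = 0.02,
                 mesh_subdiv = 4L,
                 antra_radius = 10))
  dots <- list(...)
  bad <- setdiff(names(dots), names(spec))
  if (length(bad)) stop("unknown cohort_spec fields: ", paste(bad, collapse = ", "))
  spec[names(dots)] <- dots
  for (nm in c("rs_region_dev", "fibrosis_region_mu", "fibrosis_region_sd",
               "severe_prevalence"))
    if (!all(reg %in% names(spec[[nm]]))) stop(nm, " must name all six regions")
  if (any(spec$severe_prevalence < 0 | spec$severe_prevalence > 1))
    stop("severe_prevalence must lie in [0, 1]")
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$cohort, " cohort, n = ", x$n_subjects, ", ",
      x$frames_per_cycle, " frames/cycle, seed ", x$seed, "\n", sep = "")
  cat("  pooled RS ", x$rs_mean, " +/- ", x$rs_sd, " %, LAEF ", x$laef_mean,
      " +/- ", x$laef_sd, " %, LAV ", x$lav_mean, " +/- ", x$lav_sd, " mL\n",
      sep = "")
  invisible(x)
}

# deterministic per-stage seed derivation from a subject seed
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7 + k * 104729) %% 2147483629) + 1L
}

# mean of max(X, lo) for X ~ normal(mu, sd) (floor-censored mean)
censnorm_mean <- function(mu, sd, lo) {
  z <- (lo - mu) / sd
  lo * stats::pnorm(z) + mu * stats::pnorm(z, lower.tail = FALSE) +
    sd * stats::dnorm(z)
}

# sample normal truncated to (lo, hi) by inverse CDF
rtruncnorm <- function(n, mu, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mu, sd)
  phi <- stats::pnorm(hi, mu, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mu, sd)
}

# shift delta such that the floor-truncated per-region RS mixture has the
# requested pooled mean; deterministic calibration of the generator
rs_mean_shift <- function(spec) {
  reg <- la_regions()
  s <- sqrt(spec$rs_subject_sd^2 + rs_resid_sd(spec)^2)
  target <- spec$rs_mean
  f <- function(delta) {
    mu <- spec$rs_mean + spec$rs_region_dev[reg] + delta
    mean(censnorm_mean(mu, s, spec$rs_floor)) - target
  }
  stats::uniroot(f, c(-spec$rs_sd, spec$rs_sd))$root
}

# residual (within subject-region) SD implied by the pooled SD and the
# between-region / between-subject components
rs_resid_sd <- function(spec) {
  vr <- mean(spec$rs_region_dev[la_regions()]^2)
  v <- spec$rs_sd^2 - vr - spec$rs_subject_sd^2
  if (v <= 1) stop("rs_sd too small for the configured variance components")
  sqrt(v)
}

# draw per-region reservoir-strain targets for one subject
draw_rs_targets <- function(spec, delta = rs_mean_shift(spec)) {
  reg <- la_regions()
  u <- stats::rnorm(1, 0, spec$rs_subject_sd)
  e <- stats::rnorm(6, 0, rs_resid_sd(spec))
  x <- spec$rs_mean + spec$rs_region_dev[reg] + delta + u + e
  pmax(x, spec$rs_floor)
}
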