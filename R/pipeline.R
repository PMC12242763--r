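#' Read and validate a pipeline run configuration
#'
#' YAML schema: a global `seed`, a `cohorts` map (name to [cohort_spec]
#' arguments; a cohort named `healthy` provides the Z-score normalization,
#' one named `external` is used for external evaluation), optional
#' `fibrosis` ([fibrosis_config] arguments) and `classifier`
#' (`model`, `k`, `n_perm`, `features`) blocks. Every stochastic stage
#' derives its seed deterministically from the global seed.
#'
#' @param path YAML file path, or a list already in this shape.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg$seed)) stop("config needs a global seed")
  if (is.null(cfg$cohorts) || !length(cfg$cohorts))
    stop("config needs at least one cohort")
  for (nm in names(cfg$cohorts)) {
    cc <- cfg$cohorts[[nm]]
    if (is.null(cc$n_subjects)) stop("cohort '", nm, "' needs n_subjects")
    if (is.null(cc$cohort)) stop("cohort '", nm, "' needs a cohort preset")
  }
  cfg$fibrosis <- do.call(fibrosis_config, cfg$fibrosis %||% list())
  cl <- cfg$classifier %||% list()
  cl$model <- cl$model %||% "rf"
  cl$k <- cl$k %||% 5L
  cl$n_perm <- cl$n_perm %||% 0L
  cl$features <- unlist(cl$features %||%
                          c("region", "rs", "pc2", "global_rs", "lav", "laef"))
  cfg$classifier <- cl
  structure(cfg, class = "run_config")
}

cohort_spec_from_config <- function(cfg, name) {
  cc <- cfg$cohorts[[name]]
  args <- cc
  args$seed <- cc$seed %||% derive_seed(cfg$seed, match(name, names(cfg$cohorts)))
  do.call(cohort_spec, args)
}

#' Generate all configured cohorts to disk
#'
#' @param config a [read_run_config] result (or YAML path).
#' @param out output directory; one sub-directory per cohort plus a run
#'   manifest with file hashes and the seed provenance.
#' @return the run manifest path, invisibly.
#' @export
run_generate <- function(config, out) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out, 2) != 0) stop("output path not writable: ", out)
  manifests <- list()
  for (nm in names(cfg$cohorts)) {
    spec <- cohort_spec_from_config(cfg, nm)
    cohort <- generate_cohort(spec)
    manifests[[nm]] <- write_cohort(cohort, file.path(out, nm))
  }
  run_manifest <- file.path(out, "run_manifest.json")
  jsonlite::write_json(
    list(stage = "generate", seed = cfg$seed,
         cohorts = names(cfg$cohorts),
         cohort_manifests = unname(unlist(manifests)),
         md5 = unname(tools::md5sum(unlist(manifests)))),
    run_manifest, auto_unbox = TRUE)
  invisible(run_manifest)
}

#' Read a cohort written by [write_cohort]
#' @param dir cohort directory.
#' @return an `la_cohort` (subjects carry anatomy, regions, motion,
#'   intensities and truth).
#' @export
read_cohort <- function(dir) {
  spec_path <- file.path(dir, "spec.json")
  if (!file.exists(spec_path)) stop("not a cohort directory: ", dir)
  sp <- jsonlite::read_json(spec_path, simplifyVector = TRUE)
  for (nm in c("rs_region_dev", "fibrosis_region_mu", "fibrosis_region_sd",
               "severe_prevalence"))
    sp[[nm]] <- unlist(sp[[nm]])
  spec <- structure(sp, class = "cohort_spec")
  table <- utils::read.csv(file.path(dir, "truth_table.csv"))
  table$region <- factor(table$region, levels = la_regions())
  subjects <- lapply(unique(table$subject), function(id) {
    sd <- file.path(dir, id)
    if (!dir.exists(sd)) stop("missing subject directory: ", sd)
    anat <- read_vtk(file.path(sd, "anatomy.vtk"))
    pd <- attr(anat, "point_data")
    motion <- read_motion(file.path(sd, "frame_times.json"))
    motion$reference <- anat
    tr <- jsonlite::read_json(file.path(sd, "truth.json"),
                              simplifyVector = TRUE)
    fibrosis <- as.data.frame(tr$fibrosis)
    fibrosis$region <- factor(fibrosis$region, levels = la_regions())
    structure(list(
      id = tr$id, cohort = tr$cohort, anatomy = anat,
      uac = structure(list(alpha = pd$uac_alpha, beta = pd$uac_beta),
                      class = "uac_field"),
      regions = factor(la_regions()[pd$region], levels = la_regions()),
      motion = motion,
      vertex_intensity = pd$intensity,
      blood_pool_mean = tr$blood_pool_mean,
      truth = list(rs = unlist(tr$rs),
                   volume = list(lav = tr$lav, laef = tr$laef,
                                 lav_max = max(tr$lav), lav_min = min(tr$lav)),
                   fibrosis = fibrosis)),
      class = "la_subject")
  })
  structure(list(subjects = subjects, table = table, spec = spec),
            class = "la_cohort")
}

#' Analyze generated cohorts and run the classifier harness
#'
#' Executes parcellation-derived measurements, fibrosis quantification,
#' strain feature extraction, Z-score normalization against the `healthy`
#' cohort (when present), the feature-combination classifier sweep on the
#' primary cohort, and external evaluation on the `external` cohort (when
#' present). Every stage output is persisted as CSV/JSON; with
#' `resume = TRUE`, stages whose outputs already exist are skipped.
#'
#' @param config a [read_run_config] result (or YAML path).
#' @param cohort_dir directory produced by [run_generate] (or an in-memory
#'   named list of `la_cohort`s).
#' @param out output directory.
#' @param resume skip stages whose outputs already exist.
#' @return list with feature tables, fibrosis maps, sweep and (optionally)
#'   external results, invisibly.
#' @export
run_analyze <- function(config, cohort_dir, out, resume = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cohorts <- if (is.list(cohort_dir) && !is.character(cohort_dir)) cohort_dir
  else {
    stats::setNames(lapply(names(cfg$cohorts), function(nm) {
      d <- file.path(cohort_dir, nm)
      if (!dir.exists(d))
        stop("stage analyze: missing upstream cohort artifact: ", d)
      read_cohort(d)
    }), names(cfg$cohorts))
  }
  analyses <- stats::setNames(vector("list", length(cohorts)), names(cohorts))
  tables <- analyses
  norm <- NULL
  for (nm in names(cohorts))
    analyses[[nm]] <- analyze_cohort(cohorts[[nm]], config = cfg$fibrosis)
  if ("healthy" %in% names(analyses))
    norm <- cohort_normalization(analyses$healthy$features)
  for (nm in names(cohorts))
    tables[[nm]] <- build_feature_table(analyses[[nm]], normalization = norm)
  primary <- setdiff(names(cohorts), c("healthy", "external"))[1]
  if (is.na(primary)) primary <- names(cohorts)[1]
  feat_path <- file.path(out, "features.csv")
  all_feats <- do.call(rbind, lapply(names(tables), function(nm)
    cbind(cohort_name = nm, as.data.frame(tables[[nm]]))))
  utils::write.csv(all_feats, feat_path, row.names = FALSE)
  maps <- do.call(rbind, lapply(names(analyses), function(nm) {
    a <- analyses[[nm]]
    do.call(rbind, lapply(names(a$maps), function(id)
      cbind(cohort_name = nm, subject = id, as.data.frame(a$maps[[id]]))))
  }))
  utils::write.csv(maps, file.path(out, "fibrosis_maps.csv"),
                   row.names = FALSE)
  prev <- regional_prevalence(tables[[primary]])
  utils::write.csv(data.frame(region = names(prev), prevalence_pct = prev),
                   file.path(out, "regional_prevalence.csv"),
                   row.names = FALSE)
  sweep_path <- file.path(out, "classifier_sweep.csv")
  cl <- cfg$classifier
  seed_cl <- derive_seed(cfg$seed, 97L)
  if (resume && file.exists(sweep_path)) {
    sweep <- utils::read.csv(sweep_path)
  } else {
    sweep <- feature_combination_sweep(
      tables[[primary]], setdiff(cl$features, "region"),
      model_spec = cl$model, k = cl$k, seed = seed_cl, n_perm = cl$n_perm)
    utils::write.csv(as.data.frame(sweep), sweep_path, row.names = FALSE)
    reports <- attr(sweep, "reports")
    roc <- do.call(rbind, lapply(reports, function(r)
      cbind(features = paste(r$feature_set, collapse = "+"), r$roc_points)))
    utils::write.csv(roc, file.path(out, "roc_points.csv"), row.names = FALSE)
  }
  external <- NULL
  if ("external" %in% names(tables)) {
    external <- evaluate_external(tables[[primary]], tables$external,
                                  c("region", "lav", "laef"),
                                  model_spec = cl$model, seed = seed_cl)
    jsonlite::write_json(external, file.path(out, "external_eval.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    list(stage = "analyze", seed = cfg$seed,
         config_hash = unname(tools::md5sum(feat_path)),
         primary = primary, classifier = cl[c("model", "k", "n_perm")]),
    file.path(out, "analyze_manifest.json"), auto_unbox = TRUE)
  invisible(list(tables = tables, maps = maps, sweep = sweep,
                 prevalence = prev, external = external))
}

#' Render a human-readable results summary
#'
#' Prints the classifier sweep as single-feature and pairwise matrices
#' (accuracy and AUC), the regional severe-fibrosis prevalence as text
#' bars, and the external evaluation when present. Idempotent: re-running
#' on the same results produces identical text.
#'
#' @param results_dir directory written by [run_analyze].
#' @return the summary lines, invisibly.
#' @export
run_report <- function(results_dir) {
  sweep_path <- file.path(results_dir, "classifier_sweep.csv")
  if (!file.exists(sweep_path)) stop("no classifier results in ", results_dir)
  sweep <- utils::read.csv(sweep_path)
  need <- c("features", "accuracy_mean", "accuracy_sd", "auc_mean", "auc_sd")
  miss <- setdiff(need, names(sweep))
  if (length(miss))
    stop("classifier sweep is missing columns: ", paste(miss, collapse = ", "))
  out <- c("== Severe-fibrosis classification (cross-validated) ==", "")
  single <- sweep[sweep$n_features == 1, ]
  out <- c(out, "Single features:")
  out <- c(out, sprintf("  %-12s acc %5.1f +/- %4.1f %%   AUC %.3f +/- %.3f%s",
                        single$features, single$accuracy_mean,
                        single$accuracy_sd, single$auc_mean, single$auc_sd,
                        if (!is.null(single$p_accuracy))
                          sprintf("   p = %.3g", single$p_accuracy) else ""))
  multi <- sweep[sweep$n_features > 1, ]
  if (nrow(multi)) {
    out <- c(out, "", "Feature combinations:")
    out <- c(out, sprintf("  %-24s acc %5.1f +/- %4.1f %%   AUC %.3f",
                          multi$features, multi$accuracy_mean,
                          multi$accuracy_sd, multi$auc_mean))
  }
  prev_path <- file.path(results_dir, "regional_prevalence.csv")
  if (file.exists(prev_path)) {
    prev <- utils::read.csv(prev_path)
    out <- c(out, "", "Regional severe-fibrosis prevalence:")
    out <- c(out, sprintf("  %-10s %5.1f%% %s", prev$region,
                          prev$prevalence_pct,
                          strrep("#", round(prev$prevalence_pct / 4))))
  }
  ext_path <- file.path(results_dir, "external_eval.json")
  if (file.exists(ext_path)) {
    ext <- jsonlite::read_json(ext_path, simplifyVector = TRUE)
    out <- c(out, "", sprintf(
      "External cohort: accuracy %.1f %%, AUC %.3f (n = %d rows)",
      ext$accuracy, ext$auc, ext$n_test))
  }
  cat(paste(out, collapse = "\n"), "\n")
  invisible(out)
}
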