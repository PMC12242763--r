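#' Grouped, stratified cross-validation folds
#'
#' Assigns whole subjects to folds (all six regions of a subject share a
#' fold, so global features cannot leak across the split), approximately
#' stratifying on each subject's count of severe regions.
#'
#' @param table a [build_feature_table] result (needs `subject`, `severe`).
#' @param k number of folds.
#' @param seed RNG seed for tie-breaking.
#' @param group group rows by subject (`TRUE`, default) or treat every row
#'   as its own group (plain stratified CV).
#' @return integer fold id per row of `table`.
#' @export
make_group_folds <- function(table, k = 5L, seed = 1L, group = TRUE) {
  if (k < 2L) stop("k must be >= 2")
  set.seed(seed)
  if (group) {
    sev <- tapply(table$severe, table$subject, sum)
    ord <- names(sev)[order(sev + stats::runif(length(sev)) * 0.5)]
    fold_of <- stats::setNames(rep(seq_len(k), length.out = length(ord)), ord)
    folds <- as.integer(fold_of[as.character(table$subject)])
  } else {
    ord <- order(table$severe + stats::runif(nrow(table)) * 0.5)
    folds <- integer(nrow(table))
    folds[ord] <- rep(seq_len(k), length.out = nrow(table))
  }
  folds
}

# model specs: fit returns an object, predict returns P(severe)
model_spec_impl <- function(model_spec, n_trees = 200L) {
  if (is.list(model_spec)) return(model_spec)
  switch(model_spec,
    rf = list(
      name = "rf",
      fit = function(x, y, seed) {
        df <- data.frame(x, .y = factor(y, levels = c(FALSE, TRUE)))
        ranger::ranger(.y ~ ., data = df, probability = TRUE,
                       num.trees = n_trees, seed = seed,
                       num.threads = 1L, respect.unordered.factors = TRUE)
      },
      predict = function(fit, x) {
        p <- stats::predict(fit, data = data.frame(x),
                            num.threads = 1L)$predictions
        p[, "TRUE"]
      }),
    logistic = list(
      name = "logistic",
      fit = function(x, y, seed) {
        df <- data.frame(x, .y = y)
        suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
      },
      predict = function(fit, x) {
        as.numeric(stats::predict(fit, newdata = data.frame(x),
                                  type = "response"))
      }),
    boost = list(
      name = "boost",
      fit = function(x, y, seed) {
        if (!requireNamespace("xgboost", quietly = TRUE))
          stop("xgboost not available")
        xm <- stats::model.matrix(~ . - 1, data = data.frame(x))
        set.seed(seed)
        fit <- xgboost::xgboost(data = xm, label = as.numeric(y),
                                nrounds = 50, max_depth = 3, eta = 0.2,
                                objective = "binary:logistic",
                                nthread = 1, verbose = 0)
        attr(fit, "cols") <- colnames(xm)
        fit
      },
      predict = function(fit, x) {
        xm <- stats::model.matrix(~ . - 1, data = data.frame(x))
        xm <- xm[, attr(fit, "cols"), drop = FALSE]
        as.numeric(stats::predict(fit, xm))
      }),
    stop("unknown model_spec: ", model_spec))
}

# assemble the design data.frame for a feature set, refitting PCA scores on
# the training rows only when PC features are requested
design_features <- function(table, feature_set, train_idx = NULL) {
  known <- c("region", "rs", "srate", "pc1", "pc2", "z_rs", "fibre_rs",
             "global_rs", "lav", "laef")
  bad <- setdiff(feature_set, c(known, names(table)))
  if (length(bad)) stop("unknown features: ", paste(bad, collapse = ", "))
  x <- table[, intersect(feature_set, names(table)), drop = FALSE]
  missing_cols <- setdiff(feature_set, names(table))
  if (any(c("pc1", "pc2") %in% feature_set)) {
    curves <- attr(table, "curves")
    if (is.null(curves)) {
      if (!all(c("pc1", "pc2") %in% names(table)))
        stop("PC features need curves or precomputed scores")
    } else {
      sc <- pca_scores(curves, table$region,
                       attr(table, "pca_pool") %||% "all", train_idx)
      if ("pc1" %in% feature_set) x$pc1 <- sc[, 1]
      if ("pc2" %in% feature_set) x$pc2 <- sc[, 2]
      missing_cols <- setdiff(missing_cols, c("pc1", "pc2"))
    }
  }
  if (length(missing_cols))
    stop("feature columns absent from table: ",
         paste(missing_cols, collapse = ", "))
  x[, feature_set, drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-validated severe-fibrosis classification
#'
#' K-fold cross-validation with folds grouped by subject and stratified on
#' the label, reporting per-fold accuracy and ROC AUC. PCA-score features
#' are refitted on each training fold to avoid leakage. The default model
#' is a random forest; `"logistic"` and `"boost"` are selectable, or pass a
#' custom `list(fit, predict)` spec.
#'
#' @param table a [build_feature_table] result.
#' @param feature_set character vector of feature column names (may include
#'   `pc1`/`pc2`).
#' @param model_spec `"rf"`, `"logistic"`, `"boost"`, or a custom spec.
#' @param k number of folds (default 5).
#' @param seed RNG seed (folds and model).
#' @param group group folds by subject (default `TRUE`).
#' @param n_trees forest size for the default model.
#' @return object of class `cv_report` with fold metrics and their mean/SD.
#' @export
crossval_classify <- function(table, feature_set, model_spec = "rf", k = 5L,
                              seed = 1L, group = TRUE, n_trees = 200L) {
  y <- table$severe
  if (length(unique(y)) < 2L) stop("both classes must be present")
  folds <- make_group_folds(table, k, seed, group)
  for (f in seq_len(k))
    if (length(unique(y[folds == f])) < 2L)
      stop("fold ", f, " contains a single class; ",
           "try a different stratification seed")
  ms <- model_spec_impl(model_spec, n_trees)
  acc <- auc <- numeric(k)
  roc_points <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    x <- design_features(table, feature_set, train_idx = tr)
    fit <- ms$fit(x[tr, , drop = FALSE], y[tr], seed = seed + f)
    p <- ms$predict(fit, x[te, , drop = FALSE])
    acc[f] <- 100 * mean((p > 0.5) == y[te])
    r <- pROC::roc(response = y[te], predictor = p, quiet = TRUE,
                   direction = "<", levels = c(FALSE, TRUE))
    auc[f] <- as.numeric(pROC::auc(r))
    roc_points[[f]] <- data.frame(fold = f, fpr = 1 - r$specificities,
                                  tpr = r$sensitivities)
  }
  structure(list(feature_set = feature_set, model = ms$name %||% "custom",
                 k = k, seed = seed,
                 fold_accuracy = acc, fold_auc = auc,
                 accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
                 auc_mean = mean(auc), auc_sd = stats::sd(auc),
                 roc_points = do.call(rbind, roc_points)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> [", paste(x$feature_set, collapse = " + "), "] ",
      x$model, ", ", x$k, "-fold\n", sep = "")
  cat(sprintf("  accuracy %.1f +/- %.1f %%, AUC %.3f +/- %.3f\n",
              x$accuracy_mean, x$accuracy_sd, x$auc_mean, x$auc_sd))
  if (!is.null(x$p_accuracy))
    cat(sprintf("  permutation p: accuracy %.4g, AUC %.4g (n_perm = %d)\n",
                x$p_accuracy, x$p_auc, x$n_permutations))
  invisible(x)
}

#' Plot cross-validated ROC curves
#' @param x a `cv_report`.
#' @param ... passed to [graphics::plot].
#' @export
plot.cv_report <- function(x, ...) {
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey",
                 xlab = "false positive rate", ylab = "true positive rate",
                 ...)
  for (f in unique(x$roc_points$fold)) {
    pr <- x$roc_points[x$roc_points$fold == f, ]
    pr <- pr[order(pr$fpr, pr$tpr), ]
    graphics::lines(pr$fpr, pr$tpr, col = f)
  }
  graphics::title(main = sprintf("AUC %.2f +/- %.2f", x$auc_mean, x$auc_sd))
  invisible(x)
}

#' Permutation significance of a cross-validated classifier
#'
#' Permutes the severe labels at the subject-block level (each subject's
#' six-region label vector is reassigned to another subject, preserving the
#' within-subject and region-wise label structure) and recomputes the
#' cross-validated mean accuracy and AUC. Add-one p-values:
#' `p = (1 + #\{permuted >= observed\}) / (n_perm + 1)`.
#'
#' @inheritParams crossval_classify
#' @param n_perm number of permutations (>= 99).
#' @return the observed `cv_report` with `p_accuracy`, `p_auc`,
#'   `n_permutations`, and the permuted metric vectors attached.
#' @export
permutation_pvalue <- function(table, feature_set, model_spec = "rf",
                               n_perm = 200L, k = 5L, seed = 1L,
                               group = TRUE, n_trees = 200L) {
  if (n_perm < 99L) stop("n_perm must be >= 99")
  obs <- crossval_classify(table, feature_set, model_spec, k, seed, group,
                           n_trees)
  subjects <- unique(as.character(table$subject))
  idx_of <- split(seq_len(nrow(table)), as.character(table$subject))
  perm_acc <- perm_auc <- rep(NA_real_, n_perm)
  set.seed(seed + 7919L)
  perms <- replicate(n_perm, sample(subjects), simplify = FALSE)
  for (p in seq_len(n_perm)) {
    tb <- table
    for (i in seq_along(subjects)) {
      src <- idx_of[[perms[[p]][i]]]
      dst <- idx_of[[subjects[i]]]
      # align by region when both are region-sorted tables
      tb$severe[dst] <- table$severe[src][match(table$region[dst],
                                                table$region[src])]
    }
    rep_p <- NULL
    for (try_seed in seed + c(0L, 101L, 211L, 307L, 401L)) {
      rep_p <- tryCatch(
        crossval_classify(tb, feature_set, model_spec, k, try_seed, group,
                          n_trees),
        error = function(e) NULL)
      if (!is.null(rep_p)) break
    }
    if (!is.null(rep_p)) {
      perm_acc[p] <- rep_p$accuracy_mean
      perm_auc[p] <- rep_p$auc_mean
    }
  }
  ok <- !is.na(perm_acc)
  m <- sum(ok)
  obs$p_accuracy <- (1 + sum(perm_acc[ok] >= obs$accuracy_mean)) / (m + 1)
  obs$p_auc <- (1 + sum(perm_auc[ok] >= obs$auc_mean)) / (m + 1)
  obs$n_permutations <- m
  obs$perm_accuracy <- perm_acc[ok]
  obs$perm_auc <- perm_auc[ok]
  obs
}

#' Sweep single features, pairs, and the designated triple
#'
#' Reports a cross-validated classifier for every single feature, every
#' pairwise combination of `base_features`, and the region + LAV + LAEF
#' triple.
#'
#' @inheritParams crossval_classify
#' @param base_features character vector of at least two features.
#' @param n_perm if > 0, attach permutation p-values to every report.
#' @return data.frame (class `feature_sweep`) with one row per feature set
#'   and the list of full reports as attribute `reports`.
#' @export
feature_combination_sweep <- function(table, base_features,
                                      model_spec = "rf", k = 5L, seed = 1L,
                                      n_perm = 0L, n_trees = 200L) {
  if (length(base_features) < 2L) stop("need at least 2 base features")
  sets <- c(as.list(base_features),
            utils::combn(base_features, 2, simplify = FALSE))
  triple <- c("region", "lav", "laef")
  if (all(triple %in% c(base_features, "region")))
    sets <- c(sets, list(triple))
  reports <- lapply(sets, function(fs) {
    if (n_perm > 0)
      permutation_pvalue(table, fs, model_spec, n_perm, k, seed,
                         n_trees = n_trees)
    else crossval_classify(table, fs, model_spec, k, seed, n_trees = n_trees)
  })
  out <- data.frame(
    features = vapply(sets, paste, character(1), collapse = "+"),
    n_features = lengths(sets),
    accuracy_mean = vapply(reports, `[[`, numeric(1), "accuracy_mean"),
    accuracy_sd = vapply(reports, `[[`, numeric(1), "accuracy_sd"),
    auc_mean = vapply(reports, `[[`, numeric(1), "auc_mean"),
    auc_sd = vapply(reports, `[[`, numeric(1), "auc_sd"))
  if (n_perm > 0) {
    out$p_accuracy <- vapply(reports, `[[`, numeric(1), "p_accuracy")
    out$p_auc <- vapply(reports, `[[`, numeric(1), "p_auc")
  }
  attr(out, "reports") <- reports
  class(out) <- c("feature_sweep", "data.frame")
  out
}

#' Train on one cohort, evaluate on another
#'
#' Fits the model on all of cohort A and reports accuracy and AUC on all of
#' cohort B without refitting; PCA-score features are fitted on A only.
#'
#' @param train_table,test_table [build_feature_table] results with
#'   identical feature columns.
#' @inheritParams crossval_classify
#' @return list with `accuracy`, `auc`, `n_test`.
#' @export
evaluate_external <- function(train_table, test_table, feature_set,
                              model_spec = "rf", seed = 1L, n_trees = 200L) {
  ms <- model_spec_impl(model_spec, n_trees)
  na <- nrow(train_table); nb <- nrow(test_table)
  curves <- rbind(attr(train_table, "curves"), attr(test_table, "curves"))
  tb <- rbind(as.data.frame(train_table)[,
                intersect(names(train_table), names(test_table))],
              as.data.frame(test_table)[,
                intersect(names(train_table), names(test_table))])
  missing <- setdiff(setdiff(feature_set, c("pc1", "pc2")), names(tb))
  if (length(missing))
    stop("feature columns missing from one table: ",
         paste(missing, collapse = ", "))
  attr(tb, "curves") <- curves
  attr(tb, "pca_pool") <- attr(train_table, "pca_pool") %||% "all"
  x <- design_features(tb, feature_set, train_idx = seq_len(na))
  y <- tb$severe
  fit <- ms$fit(x[seq_len(na), , drop = FALSE], y[seq_len(na)], seed = seed)
  p <- ms$predict(fit, x[na + seq_len(nb), , drop = FALSE])
  yte <- y[na + seq_len(nb)]
  r <- pROC::roc(response = yte, predictor = p, quiet = TRUE,
                 direction = "<", levels = c(FALSE, TRUE))
  list(accuracy = 100 * mean((p > 0.5) == yte),
       auc = as.numeric(pROC::auc(r)), n_test = nb)
}

#' Regional prevalence of severe fibrosis
#'
#' Percent of subjects with severe fibrosis in each region.
#'
#' @param x an `la_cohort`, a cohort truth/feature table, or a list of
#'   `fibrosis_map`s.
#' @return named numeric vector (%), one entry per region.
#' @export
regional_prevalence <- function(x) {
  if (inherits(x, "la_cohort")) tb <- x$table
  else if (is.data.frame(x)) tb <- x
  else {
    tb <- do.call(rbind, lapply(seq_along(x), function(i) {
      m <- x[[i]]
      data.frame(subject = i, region = m$region, severe = m$severe)
    }))
  }
  if (!nrow(tb)) stop("need at least one subject")
  100 * vapply(split(tb$severe, factor(tb$region, levels = la_regions())),
               mean, numeric(1))
}
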