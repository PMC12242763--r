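test_that("a perfectly separating feature classifies perfectly", {
  tb <- toy_table(30, seed = 2, signal = 10)
  r <- crossval_classify(tb, "sig", model_spec = "rf", seed = 4,
                         n_trees = 100)
  expect_gt(r$accuracy_mean, 97)
  expect_gt(r$auc_mean, 0.995)
  rl <- crossval_classify(tb, "sig", model_spec = "logistic", seed = 4)
  expect_gt(rl$auc_mean, 0.995)
})

test_that("null features stay within the majority-class binomial band", {
  tb <- toy_table(47, seed = 5, p_severe = 0.6)
  r <- crossval_classify(tb, "noise", model_spec = "rf", seed = 6,
                         n_trees = 100)
  base <- max(mean(tb$severe), 1 - mean(tb$severe))
  hw <- 1.96 * sqrt(base * (1 - base) / nrow(tb))
  expect_lt(r$accuracy_mean / 100, base + hw + 0.02)
  expect_gt(r$accuracy_mean / 100, 2 * base - 1 - hw - 0.02)
})

test_that("cross-validation reports are seed-deterministic", {
  tb <- toy_table(20, seed = 8, signal = 1)
  r1 <- crossval_classify(tb, c("sig", "noise"), seed = 11, n_trees = 50)
  r2 <- crossval_classify(tb, c("sig", "noise"), seed = 11, n_trees = 50)
  expect_identical(r1$fold_accuracy, r2$fold_accuracy)
  expect_identical(r1$fold_auc, r2$fold_auc)
})

test_that("single-class folds raise an actionable error", {
  tb <- toy_table(6, seed = 1, p_severe = 0.5)
  tb$severe <- rep(c(TRUE, FALSE), each = 18)  # 3 subjects all-severe
  expect_error(crossval_classify(tb, "noise", k = 6), "single class")
  expect_error(crossval_classify(tb[tb$severe, ], "noise"), "both classes")
})

test_that("held-out folds are untouched by training-only signal", {
  # feature equals the label for subjects in one fold and noise in the
  # other; the contaminated fold trains a perfect rule whose held-out
  # accuracy must collapse to chance if evaluation is honest
  tb <- toy_table(24, seed = 3)
  folds <- make_group_folds(tb, k = 2, seed = 13)
  leak <- ifelse(folds == 1, as.numeric(tb$severe), rnorm(nrow(tb)))
  tb$leak <- leak
  r <- crossval_classify(tb, "leak", k = 2, seed = 13, n_trees = 100)
  expect_lt(r$fold_accuracy[2], 70)
  expect_lt(r$fold_auc[2], 0.7)
})

test_that("PCA features are refit inside training folds", {
  ch <- small_af_cohort()
  ft <- build_feature_table(analyze_cohort(ch))
  r <- crossval_classify(ft, c("pc1", "pc2"), k = 2, seed = 5, n_trees = 50)
  expect_true(is.finite(r$auc_mean))
  # scores from a half-table fit differ from full-table scores
  half <- seq_len(24)
  sc_half <- lastrain:::pca_scores(attr(ft, "curves"), ft$region, "all",
                                   train_idx = half)
  sc_full <- lastrain:::pca_scores(attr(ft, "curves"), ft$region, "all")
  expect_false(isTRUE(all.equal(sc_half[, 1], sc_full[, 1])))
})

test_that("grouping with singleton subjects reduces to stratified CV", {
  tb <- toy_table(10, seed = 4)
  tb <- tb[!duplicated(tb$subject), ]   # one row per subject
  tb$subject <- paste0(tb$subject, "_", seq_len(nrow(tb)))
  fg <- make_group_folds(tb, k = 2, seed = 9, group = TRUE)
  fu <- make_group_folds(tb, k = 2, seed = 9, group = FALSE)
  balance <- function(f) sort(tapply(tb$severe, f, sum))
  expect_equal(unname(balance(fg)), unname(balance(fu)))
  expect_equal(sort(unname(table(fg))), sort(unname(table(fu))))
})

test_that("permutation p-values hit the analytic extremes", {
  tb <- toy_table(20, seed = 6, signal = 10)
  r <- permutation_pvalue(tb, "sig", model_spec = "logistic", n_perm = 99,
                          seed = 3)
  expect_equal(r$p_auc, 1 / 100)
  const <- toy_table(20, seed = 7)
  const$flat <- 0.5
  rc <- permutation_pvalue(const, "flat", model_spec = "logistic",
                           n_perm = 99, seed = 3)
  expect_gt(rc$p_accuracy, 0.5)
  expect_error(permutation_pvalue(tb, "sig", n_perm = 50), ">= 99")
})

test_that("feature sweeps enumerate singletons, pairs and the triple", {
  ch <- small_af_cohort()
  ft <- build_feature_table(analyze_cohort(ch))
  sw <- feature_combination_sweep(ft, c("rs", "lav", "laef"),
                                  model_spec = "logistic", k = 2, seed = 2)
  expect_equal(sum(sw$n_features == 1), 3L)
  expect_equal(sum(sw$n_features == 2), 3L)
  expect_equal(sum(sw$n_features == 3), 1L)
  expect_equal(sw$features[sw$n_features == 3], "region+lav+laef")
})

test_that("external evaluation refuses mismatched tables and matches resubstitution", {
  tb <- toy_table(20, seed = 9, signal = 3)
  r <- evaluate_external(tb, tb, "sig", model_spec = "logistic", seed = 1)
  ms <- lastrain:::model_spec_impl("logistic")
  fit <- ms$fit(tb[, "sig", drop = FALSE], tb$severe, 1)
  p <- ms$predict(fit, tb[, "sig", drop = FALSE])
  expect_equal(r$accuracy, 100 * mean((p > 0.5) == tb$severe))
  tb2 <- tb
  tb2$sig <- NULL
  expect_error(evaluate_external(tb, tb2, "sig"), "missing")
})

test_that("regional prevalence equals the direct tally", {
  ch <- small_af_cohort()
  prev <- regional_prevalence(ch)
  tb <- ch$table
  for (r in la_regions())
    expect_equal(unname(prev[r]),
                 100 * sum(tb$severe[tb$region == r]) / 8)
  all_sev <- tb
  all_sev$severe <- TRUE
  expect_equal(unname(regional_prevalence(all_sev)), rep(100, 6))
})
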