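test_that("reservoir strain is the curve amplitude", {
  expect_equal(reservoir_strain(c(0, 30, 0)), 30)
  expect_equal(reservoir_strain(rep(4, 10)), 0)
  set.seed(3)
  x <- rnorm(40)
  expect_equal(reservoir_strain(x), max(x) - min(x))
  expect_error(reservoir_strain(c(1, 2)), "3 frames")
})

test_that("peak strain rate matches analytic slopes", {
  n <- 40
  t <- (0:(n - 1)) / n
  expect_equal(peak_strain_rate(rep(2, n), t), 0)
  expect_equal(peak_strain_rate(5 * t, t, periodic = FALSE), 5,
               tolerance = 1e-12)
  sine <- sin(2 * pi * t)
  # analytic peak derivative 2*pi; central differences underestimate by
  # sin(h)/h with h = 2*pi/n
  h <- 2 * pi / n
  expect_equal(peak_strain_rate(sine, t), 2 * pi * sin(h) / h,
               tolerance = 1e-6)
  expect_error(peak_strain_rate(sine, c(0, 0, t[-(1:2)])), "duplicate")
})

test_that("PCA recovers a planted two-factor structure", {
  set.seed(7)
  t <- (0:29) / 30
  b1 <- sin(pi * t)^2
  b2 <- sin(2 * pi * t)
  a <- rnorm(80, 0, 3)
  b <- rnorm(80, 0, 1.5)
  b <- residuals(lm(b ~ a))   # empirically uncorrelated factor pair
  curves <- outer(a, b1) + outer(b, b2)
  fit <- fit_strain_pca(curves)
  expect_gt(sum(fit$var_explained[1:2]), 0.99)
  sc <- project_strain_pca(fit, curves, 2)
  expect_gt(abs(cor(sc[, 1], a)), 0.99)
  expect_gt(abs(cor(sc[, 2], b)), 0.99)
  G <- t(fit$loadings) %*% fit$loadings
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-9)
  expect_lt(max(abs(project_strain_pca(fit, fit$mean, 2))), 1e-9)
  expect_error(fit_strain_pca(curves[c(1, 1), ]), "rank 0")
})

test_that("z-scores normalize against healthy per-region parameters", {
  norm <- data.frame(region = factor(la_regions(), levels = la_regions()),
                     mu_healthy = rep(48.0, 6), sd_healthy = rep(33.2, 6))
  class(norm) <- c("cohort_normalization", "data.frame")
  expect_equal(zscore(48.0, norm, "septal"), 0)
  expect_equal(round(zscore(19.5, norm, "lateral"), 4), -0.8584)
  expect_error(zscore(10, norm, "apex"), "missing")
  ft <- build_feature_table(analyze_cohort(small_healthy_cohort()))
  self <- cohort_normalization(ft)
  z <- zscore(ft$rs, self, ft$region)
  for (r in la_regions()) {
    expect_lt(abs(mean(z[ft$region == r])), 1e-9)
    expect_lt(abs(sd(z[ft$region == r]) - 1), 1e-9)
  }
  bad <- ft
  bad$rs <- rep(1, nrow(bad))
  expect_error(cohort_normalization(bad), "sd_healthy")
})

test_that("feature tables join subject, strain and fibrosis outputs", {
  ch <- small_af_cohort()
  an <- analyze_cohort(ch)
  norm <- cohort_normalization(analyze_cohort(small_healthy_cohort())$features)
  ft <- build_feature_table(an, normalization = norm)
  expect_equal(nrow(ft), 8 * 6)
  expect_true(all(c("region", "rs", "srate", "pc1", "pc2", "z_rs",
                    "global_rs", "lav", "laef", "severe") %in% names(ft)))
  for (s in unique(ft$subject)) {
    rows <- ft[ft$subject == s, ]
    expect_equal(length(unique(rows$lav)), 1L)
    expect_equal(length(unique(rows$laef)), 1L)
    expect_equal(length(unique(rows$global_rs)), 1L)
  }
  # labels match the fibrosis maps exactly
  lab <- unlist(lapply(an$maps, function(m) m$severe))
  expect_equal(ft$severe, unname(lab))
  expect_identical(dim(attr(ft, "curves")), c(48L, 30L))
})

test_that("measured features agree with generator truth", {
  ch <- small_af_cohort()
  an <- analyze_cohort(ch)
  expect_equal(an$features$enhancement_pct, ch$table$enhancement_pct,
               tolerance = 0.05)
  expect_equal(an$features$severe, ch$table$severe)
  expect_equal(an$features$lav, ch$table$lav, tolerance = 1e-3)
  expect_equal(an$features$rs, ch$table$rs_true, tolerance = 0.2)
})
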