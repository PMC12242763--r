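test_that("anatomy generation is deterministic and volume-exact", {
  spec <- test_spec(1, "AF", seed = 1)
  a1 <- generate_anatomy(spec, 42L, volume_target = 80)
  a2 <- generate_anatomy(spec, 42L, volume_target = 80)
  expect_identical(a1, a2)
  expect_equal(enclosed_volume(a1), 80, tolerance = 0.02)
  expect_true(validate_mesh(a1))
  expect_setequal(unique(a1$labels),
                  c("body", "mitral_rim", "LAA", "LSPV", "LIPV", "RSPV",
                    "RIPV"))
  need <- c("LSPV_junction", "LIPV_junction", "RSPV_junction",
            "RIPV_junction", "mitral_ring", "lateral_anchor",
            "septal_anchor", "posterior_anchor", "anterior_anchor")
  expect_true(all(need %in% names(a1$landmarks)))
  expect_true(all(lengths(a1$landmarks[need]) > 0))
})

test_that("uniform-scaling motion obeys the scaling law", {
  spec <- test_spec(1, "AF", seed = 1, motion_jitter_sd = 0)
  an <- generate_anatomy(spec, 7L, volume_target = 70)
  mo <- generate_motion(an, spec, 8L, uniform_lambda = 1.12)
  es <- area_strain(mo)
  g <- cycle_shape(mo$frame_times)
  lam_t <- 1 + 0.12 * g
  for (i in c(5, 14, 22))
    expect_lt(max(abs(es[, i] - 100 * (lam_t[i]^2 - 1))), 1e-9)
})

test_that("three-frame sequences are valid minimal cycles", {
  spec <- test_spec(1, "AF", seed = 1, frames_per_cycle = 3,
                    motion_jitter_sd = 0)
  s <- generate_subject(spec, 3L)
  expect_length(s$motion$frames, 3L)
  expect_equal(s$motion$frames[[1]], s$anatomy$vertices)
})

test_that("motion calibration hits the drawn regional reservoir strains", {
  s <- clean_subject()
  # narrow regions bordered by stronger neighbours keep a bounded residual;
  # the global amplitude step pins the subject mean
  expect_lt(abs(mean(s$truth$rs - s$truth$rs_targets)), 0.5)
  expect_lt(max(abs(s$truth$rs - s$truth$rs_targets)), 8)
})

test_that("pooled healthy reservoir strain converges to the cohort mean", {
  tb <- healthy_cohort_200()$table
  expect_lt(abs(mean(tb$rs_true) - 48.0), 3)
})

test_that("cohort generation is seed-deterministic and correctly shaped", {
  spec <- test_spec(2, "AF", seed = 9)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$table, c2$table)
  expect_identical(c1$subjects[[2]]$vertex_intensity,
                   c2$subjects[[2]]$vertex_intensity)
  c3 <- generate_cohort(test_spec(2, "AF", seed = 10))
  expect_false(identical(c1$table$enhancement_pct, c3$table$enhancement_pct))
  tb <- af_cohort_47()$table
  expect_equal(nrow(tb), 47 * 6)
  expect_equal(unname(table(tb$region)), rep(47L, 6),
               ignore_attr = TRUE)
})

test_that("healthy cohorts stay below the severe-fibrosis cap", {
  ch <- healthy_cohort_200()
  cap <- max(ch$spec$severe_prevalence) + 0.04
  expect_lt(mean(ch$table$severe), cap)
})

test_that("zeroed burden and links paint no enhancement", {
  spec <- test_spec(1, "AF", seed = 2, intensity_noise_sd = 0,
                    motion_jitter_sd = 0,
                    link_lav = 0, link_laef = 0,
                    fibrosis_region_mu = stats::setNames(rep(0, 6),
                                                         la_regions()),
                    severe_prevalence = stats::setNames(rep(1e-4, 6),
                                                        la_regions()))
  s <- generate_subject(spec, 11L)
  iir <- compute_iir(s$vertex_intensity, s$blood_pool_mean)
  expect_true(all(iir < 1.2))
  expect_equal(s$truth$fibrosis$enhancement_pct, rep(0, 6))
})

test_that("painted enhancement fractions close through the quantification path", {
  spec <- test_spec(1, "AF", seed = 3, intensity_noise_sd = 0,
                    motion_jitter_sd = 0,
                    fibrosis_region_mu = stats::setNames(rep(50, 6),
                                                         la_regions()),
                    fibrosis_region_sd = stats::setNames(rep(0.01, 6),
                                                         la_regions()),
                    severe_prevalence = stats::setNames(rep(1 - 1e-4, 6),
                                                        la_regions()))
  s <- generate_subject(spec, 13L)
  map <- regional_enhancement(compute_iir(s$vertex_intensity,
                                          s$blood_pool_mean),
                              s$regions, s$anatomy)
  expect_lt(max(abs(map$enhancement_pct - 50)), 2.5)
  expect_equal(map$enhancement_pct, s$truth$fibrosis$enhancement_pct,
               tolerance = 1e-9)
})

test_that("regional strain and enhancement stay decoupled at zero coupling", {
  tb <- af_cohort_200()$table
  expect_lt(abs(cor(tb$rs_true, tb$enhancement_pct)), 0.1)
})

test_that("the lateral wall carries the highest severe-fibrosis prevalence", {
  prev <- regional_prevalence(af_cohort_200())
  expect_equal(names(which.max(prev)), "lateral")
  expect_lt(prev["LPVA"], prev["lateral"])
})
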