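test_that("image intensity ratio is elementwise division", {
  expect_equal(compute_iir(120, 100), 1.2)
  expect_equal(compute_iir(0, 50), 0)
  set.seed(1)
  x <- runif(100, 0, 300)
  expect_identical(compute_iir(x, 87.3), x / 87.3)
  expect_error(compute_iir(x, 0), "positive")
  expect_error(compute_iir(x, -3), "positive")
})

test_that("staging follows the half-open intervals with severe strictly above 30", {
  st <- stage_enhancement(c(5, 15, 25, 35, 30, 10, 20, 0, 100))
  expect_equal(st$stage, c(1L, 2L, 3L, 4L, 3L, 2L, 3L, 1L, 4L))
  expect_equal(st$severe, c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                            FALSE, TRUE))
  expect_error(stage_enhancement(-1), "\\[0, 100\\]")
  expect_error(stage_enhancement(101), "\\[0, 100\\]")
  expect_error(fibrosis_config(stage_bounds = c(10, 10, 30)), "increasing")
  expect_error(fibrosis_config(iir_threshold = 0), "> 0")
})

test_that("regional enhancement covers the saturated and empty extremes", {
  s <- clean_subject()
  n <- nrow(s$anatomy$vertices)
  hot <- regional_enhancement(rep(1.5, n), s$regions, s$anatomy)
  expect_equal(hot$enhancement_pct, rep(100, 6))
  expect_equal(hot$stage, rep(4L, 6))
  expect_true(all(hot$severe))
  cfg_hi <- fibrosis_config(iir_threshold = 2)
  cold <- regional_enhancement(rep(1.5, n), s$regions, s$anatomy, cfg_hi)
  expect_equal(cold$enhancement_pct, rep(0, 6))
  expect_equal(cold$stage, rep(1L, 6))
})

test_that("regional enhancement equals the per-triangle oracle", {
  s <- clean_subject()
  iir <- compute_iir(s$vertex_intensity, s$blood_pool_mean)
  cfg <- fibrosis_config()
  map <- regional_enhancement(iir, s$regions, s$anatomy, cfg)
  treg <- triangle_regions(s$anatomy, s$regions)
  a <- triangle_areas(s$anatomy)
  tri <- s$anatomy$triangles
  for (r in c("posterior", "lateral")) {
    sel <- which(treg == r)
    enh <- vapply(sel, function(t)
      mean(iir[tri[t, ]]) > cfg$iir_threshold, logical(1))
    expect_equal(map$enhancement_pct[map$region == r],
                 100 * sum(a[sel][enh]) / sum(a[sel]), tolerance = 1e-12)
  }
})

test_that("enhancement is monotone in the threshold and conserved globally", {
  s <- clean_subject()
  iir <- compute_iir(s$vertex_intensity, s$blood_pool_mean)
  thr <- seq(0.8, 1.8, by = 0.1)
  curves <- sapply(thr, function(th)
    regional_enhancement(iir, s$regions, s$anatomy,
                         fibrosis_config(iir_threshold = th))$enhancement_pct)
  expect_true(all(diff(t(curves)) <= 1e-12))
  map <- regional_enhancement(iir, s$regions, s$anatomy)
  treg <- triangle_regions(s$anatomy, s$regions)
  a <- triangle_areas(s$anatomy)
  w <- vapply(la_regions(), function(r) sum(a[which(treg == r)]), numeric(1))
  expect_equal(attr(map, "whole_surface_pct"),
               sum(map$enhancement_pct * w) / sum(w), tolerance = 1e-9)
})

test_that("image projection samples the wall band correctly", {
  s <- clean_subject()
  box <- apply(s$anatomy$vertices, 2, range)
  uni <- la_image(array(7, dim = c(30, 30, 30)),
                  spacing = (box[2, ] - box[1, ] + 12) / 30,
                  origin = box[1, ] - 6)
  expect_equal(project_image_to_surface(uni, s$anatomy, depth = 3),
               rep(7, nrow(s$anatomy$vertices)))
  expect_equal(project_image_to_surface(uni, s$anatomy, depth = 0),
               rep(7, nrow(s$anatomy$vertices)))
  tiny <- la_image(array(1, dim = c(4, 4, 4)), spacing = c(1, 1, 1),
                   origin = c(0, 0, 0))
  expect_error(project_image_to_surface(tiny, s$anatomy, depth = 1),
               "vertex [0-9]+ samples")
})

test_that("voxelized subject round-trips through surface projection", {
  s <- clean_subject()
  img <- voxelize_intensity(s, voxel_size = 1.5)
  proj <- project_image_to_surface(img, s$anatomy, depth = 3)
  expect_gt(cor(proj, s$vertex_intensity), 0.95)
  bp <- estimate_blood_pool_mean(img, s$anatomy)
  expect_equal(bp, s$blood_pool_mean, tolerance = 0.02)
  expect_warning(voxelize_intensity(s, voxel_size = 8), "lossy")
})

test_that("blood-pool estimation averages the eroded cavity", {
  s <- clean_subject()
  box <- apply(s$anatomy$vertices, 2, range)
  sp <- (box[2, ] - box[1, ] + 12) / 40
  org <- box[1, ] - 6
  uni <- la_image(array(100, dim = c(40, 40, 40)), spacing = sp, origin = org)
  expect_equal(estimate_blood_pool_mean(uni, s$anatomy), 100,
               tolerance = 1e-9)
  # two-valued cavity of equal volumes averages to the midpoint: use a
  # centred sphere so the x > 0 / x < 0 halves have exactly equal volume
  sph <- icosphere(3, 20)
  sp2 <- rep(1.25, 3)
  org2 <- c(-24.375, -24.375, -24.375)   # first voxel centre
  xs <- org2[1] + (seq_len(40) - 1) * sp2[1]
  two <- array(rep(ifelse(xs < 0, 50, 150), times = 1600),
               dim = c(40, 40, 40))
  est <- estimate_blood_pool_mean(la_image(two, sp2, org2), sph,
                                  n_samples = 20000L)
  expect_equal(est, 100, tolerance = 0.02)
})
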