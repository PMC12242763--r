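make_uniform_motion <- function(lambda = 1.1, n_frames = 3) {
  m <- icosphere(2, 10)
  ctr <- colMeans(m$vertices)
  sc <- seq(1, lambda, length.out = n_frames)
  frames <- lapply(sc, function(s)
    sweep(sweep(m$vertices, 2, ctr, "-") * s, 2, ctr, "+"))
  mesh_motion(m, frames)
}

test_that("uniform scaling gives the analytic area strain on every element", {
  mo <- make_uniform_motion(1.1, 3)
  es <- area_strain(mo)
  expect_lt(max(abs(es[, 3] - 100 * (1.1^2 - 1))), 1e-9)
  expect_equal(es[, 1], rep(0, nrow(es)))
})

test_that("rigid motion produces zero strain", {
  m <- icosphere(2, 10)
  th <- 0.4
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  frames <- list(m$vertices, m$vertices %*% t(R) + 2,
                 m$vertices %*% t(R %*% R) - 5)
  es <- area_strain(mesh_motion(m, frames))
  expect_lt(max(abs(es)), 1e-9)
})

test_that("area strain equals direct triangle-area recomputation", {
  set.seed(4)
  m <- icosphere(1, 6)
  pert <- m$vertices + matrix(rnorm(length(m$vertices), 0, 0.3), ncol = 3)
  mo <- mesh_motion(m, list(m$vertices, pert, m$vertices))
  es <- area_strain(mo)
  a0 <- triangle_areas(m)
  a1 <- triangle_areas(pert, m$triangles)
  expect_equal(es[, 2], 100 * (a1 - a0) / a0, tolerance = 1e-12)
})

test_that("regional curves reduce to the global curve for uniform motion", {
  s <- clean_subject()
  spec1 <- test_spec(1, "AF", seed = 1, motion_jitter_sd = 0)
  mo <- generate_motion(s$anatomy, spec1, 5, uniform_lambda = 1.08)
  es <- area_strain(mo)
  sc <- regional_strain_curves(es, s$regions, mo)
  for (r in la_regions())
    expect_equal(sc$regional[r, ], sc$global, tolerance = 1e-9,
                 ignore_attr = TRUE)
  # and equals the area-sum oracle under mixed motion
  mo2 <- s$motion
  es2 <- area_strain(mo2)
  sc2 <- regional_strain_curves(es2, s$regions, mo2)
  treg <- triangle_regions(s$anatomy, s$regions)
  a0 <- triangle_areas(s$anatomy)
  sel <- which(treg == "septal")
  at <- triangle_areas(mo2$frames[[10]], s$anatomy$triangles)
  expect_equal(unname(sc2$regional["septal", 10]),
               100 * (sum(at[sel]) - sum(a0[sel])) / sum(a0[sel]),
               tolerance = 1e-9)
})

test_that("fibre strain follows principal stretches", {
  s <- strip_mesh(6, 4)
  m <- s$mesh
  fib_x <- matrix(rep(c(1, 0, 0), each = nrow(m$triangles)),
                  ncol = 3)
  fib_y <- matrix(rep(c(0, 1, 0), each = nrow(m$triangles)), ncol = 3)
  lam <- 1.25
  stretch_x <- m$vertices %*% diag(c(lam, 1, 1))
  mo <- mesh_motion(m, list(m$vertices, stretch_x, m$vertices))
  expect_lt(max(abs(fibre_strain(mo, fib_x)[, 2] - 100 * (lam - 1))), 1e-9)
  expect_lt(max(abs(fibre_strain(mo, fib_y)[, 2])), 1e-9)
  iso <- m$vertices * lam
  mo2 <- mesh_motion(m, list(m$vertices, iso, m$vertices))
  set.seed(2)
  ang <- runif(nrow(m$triangles), 0, 2 * pi)
  fib_r <- cbind(cos(ang), sin(ang), 0)
  expect_lt(max(abs(fibre_strain(mo2, fib_r)[, 2] - 100 * (lam - 1))), 1e-9)
  # random affine matches an explicit material-segment oracle
  A <- rbind(c(1.2, 0.3, 0), c(-0.1, 0.9, 0), c(0.05, 0, 1))
  mo3 <- mesh_motion(m, list(m$vertices, m$vertices %*% t(A), m$vertices))
  fs <- fibre_strain(mo3, fib_r)[, 2]
  oracle <- 100 * (sqrt(rowSums((fib_r %*% t(A))^2)) - 1)
  expect_equal(fs, oracle, tolerance = 1e-9)
})

test_that("volume curve yields LAV extremes and LAEF", {
  mo <- make_uniform_motion(1.0, 3)
  vc0 <- volume_curve(mo, exclude = character(0))
  expect_equal(vc0$laef, 0)
  lam <- (1 / 0.4)^(1 / 3)   # V_min / V_max = 0.4 exactly
  m <- icosphere(2, 10)
  frames <- list(m$vertices, m$vertices * lam, m$vertices)
  vc <- volume_curve(mesh_motion(m, frames), exclude = character(0))
  expect_equal(vc$laef, 60, tolerance = 1e-9)
})

test_that("cyclic resampling preserves phase 0 and linear segments", {
  x <- (0:49) / 50
  ramp <- 3 * x
  out <- resample_curve(ramp, x, 30)
  expect_equal(out, 3 * (0:29) / 30, tolerance = 1e-12)
  expect_equal(resample_curve(ramp, x, length(x)), ramp, tolerance = 1e-12)
  sine <- sin(2 * pi * x)
  rs <- resample_curve(sine, x, 30)
  bound <- (2 * pi)^2 / (8 * 50^2)
  expect_lt(max(abs(rs - sin(2 * pi * (0:29) / 30))), bound * 1.01)
  expect_error(resample_curve(ramp, x, 2), ">= 3")
  expect_error(resample_curve(c(1, 2), c(0, 0.5), 10), "3 input frames")
})

test_that("motion containers enforce their contracts", {
  m <- icosphere(1, 5)
  expect_error(mesh_motion(m, list(m$vertices, m$vertices)), "3 frames")
  expect_error(mesh_motion(m, list(m$vertices + 1, m$vertices, m$vertices)),
               "frame 0")
  deg <- la_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0)),
                 rbind(c(1, 2, 4), c(1, 2, 3)), validate = FALSE)
  mo <- structure(list(reference = deg,
                       frames = list(deg$vertices, deg$vertices,
                                     deg$vertices),
                       frame_times = c(0, 0.3, 0.6)),
                  class = "mesh_motion")
  expect_error(area_strain(mo), "zero reference")
})
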