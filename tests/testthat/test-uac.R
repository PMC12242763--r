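test_that("harmonic field on a strip reproduces the linear closed form", {
  s <- strip_mesh(11, 4)
  h <- harmonic_field(s$mesh, list(
    list(vertices = s$left, value = 0),
    list(vertices = s$right, value = 1)))
  expect_lt(max(abs(h - s$x)), 1e-6)
})

test_that("harmonic field obeys the discrete maximum principle", {
  s <- strip_mesh(9, 5)
  h0 <- harmonic_field(s$mesh, list(
    list(vertices = s$left, value = 0),
    list(vertices = s$right, value = 0)))
  expect_equal(as.numeric(h0), rep(0, length(h0)))
  an <- clean_subject()$anatomy
  uac <- clean_subject()$uac
  lm <- an$landmarks
  dirichlet <- c(lm$lateral_anchor, lm$septal_anchor)
  interior <- setdiff(seq_len(nrow(an$vertices)), dirichlet)
  expect_true(all(uac$alpha[interior] > 0 & uac$alpha[interior] < 1))
  expect_true(all(uac$alpha[lm$lateral_anchor] == 0))
  expect_true(all(uac$alpha[lm$septal_anchor] == 1))
})

test_that("harmonic boundary errors are caught", {
  s <- strip_mesh(6, 3)
  expect_error(harmonic_field(s$mesh, list(
    list(vertices = 1:4, value = 0),
    list(vertices = 3:6, value = 1))), "overlap")
  expect_error(harmonic_field(s$mesh, list(
    list(vertices = integer(0), value = 0))), "non-empty")
  two <- s$mesh
  m2 <- strip_mesh(6, 3)$mesh
  two$vertices <- rbind(two$vertices, m2$vertices + 5)
  two$triangles <- rbind(two$triangles, m2$triangles + nrow(s$mesh$vertices))
  two$labels <- rep("body", nrow(two$vertices))
  expect_error(harmonic_field(two, list(
    list(vertices = s$left, value = 0),
    list(vertices = s$right, value = 1))), "disconnected")
})

test_that("geodesic distance matches the path graph and brute force", {
  # straight chain of unit edges embedded as a thin strip
  s <- strip_mesh(8, 2, height = 1e-3)
  d <- geodesic_distance(s$mesh, which(s$x == 0 & s$y == 0))
  along <- which(s$y == 0)
  expect_equal(d[along], s$x[along] * 1, tolerance = 1e-9)
  expect_equal(geodesic_distance(s$mesh, seq_len(nrow(s$mesh$vertices))),
               rep(0, nrow(s$mesh$vertices)))
  expect_error(geodesic_distance(s$mesh, integer(0)), "non-empty")
  m <- icosphere(1, 3)
  seeds <- c(2L, 7L)
  expect_equal(geodesic_distance(m, seeds), brute_geodesic(m, seeds),
               tolerance = 1e-9)
})

test_that("fibre transfer is exact under identity and rigid rotation", {
  s <- clean_subject()
  fib <- lastrain:::fibre_frames(s$anatomy, s$uac)$e1
  same <- map_fibres(fib, s$anatomy, s$uac, s$anatomy, s$uac)
  expect_lt(max(abs(rowSums(fib * same) - 1)), 1e-9)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- s$anatomy
  rot$vertices <- s$anatomy$vertices %*% t(R)
  uac_rot <- build_uac(rot)
  mapped <- map_fibres(fib, s$anatomy, s$uac, rot, uac_rot)
  expect_lt(max(abs(mapped - fib %*% t(R))), 1e-9)
  # fibres are unit tangents
  nrm <- triangle_normals(rot)
  expect_lt(max(abs(rowSums(mapped * nrm))), 1e-9)
  expect_equal(rowSums(mapped^2), rep(1, nrow(mapped)), tolerance = 1e-12)
})
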