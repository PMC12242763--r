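test_that("icosphere volume matches the closed form within 0.5%", {
  m <- icosphere(4, 10)
  expect_equal(enclosed_volume(m, exclude = character(0)), 4.18879,
               tolerance = 5e-3)
})

test_that("volume is rigid-motion invariant and scales as lambda^3", {
  m <- icosphere(2, 8)
  v0 <- enclosed_volume(m, exclude = character(0))
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  moved <- m
  moved$vertices <- m$vertices %*% t(R) + matrix(c(3, -7, 11), nrow(m$vertices),
                                                 3, byrow = TRUE)
  expect_lt(abs(enclosed_volume(moved, exclude = character(0)) / v0 - 1),
            1e-8)
  scaled <- m
  scaled$vertices <- m$vertices * 1.7
  expect_equal(enclosed_volume(scaled, exclude = character(0)), v0 * 1.7^3,
               tolerance = 1e-12)
})

test_that("capped, stub-excluded volume agrees with a ray-casting fill", {
  an <- clean_subject()$anatomy
  v <- enclosed_volume(an)
  keep <- !(an$labels[an$triangles[, 1]] %in%
              c("LAA", "LSPV", "LIPV", "RSPV", "RIPV") |
              an$labels[an$triangles[, 2]] %in%
              c("LAA", "LSPV", "LIPV", "RSPV", "RIPV") |
              an$labels[an$triangles[, 3]] %in%
              c("LAA", "LSPV", "LIPV", "RSPV", "RIPV"))
  capped <- lastrain:::cap_boundaries(submesh(an, keep)$mesh)
  oracle <- raycast_volume(capped$vertices, capped$triangles, h = 1)
  expect_equal(v, oracle, tolerance = 1e-2)
})

test_that("unclosable surfaces raise errors", {
  m <- icosphere(2, 5)
  flip <- m
  flip$triangles[3, ] <- flip$triangles[3, c(2, 1, 3)]
  expect_error(enclosed_volume(flip, exclude = character(0)),
               "orientable|oriented|closed")
  all_lab <- m
  all_lab$labels <- rep("LAA", nrow(m$vertices))
  expect_error(enclosed_volume(all_lab), "no triangles")
})
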