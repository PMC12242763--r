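test_that("icosphere approximates a sphere and passes mesh invariants", {
  m <- icosphere(3, 10)
  expect_true(validate_mesh(m))
  expect_equal(sum(triangle_areas(m)), 4 * pi * 100, tolerance = 5e-3)
  n <- triangle_normals(m)
  expect_equal(rowSums(n^2), rep(1, nrow(n)), tolerance = 1e-12)
})

test_that("mesh validation rejects broken surfaces", {
  m <- icosphere(1)
  bad <- m
  bad$triangles[1, ] <- c(1L, 1L, 2L)
  expect_error(validate_mesh(bad), "degenerate")
  flip <- m
  flip$triangles[1, ] <- flip$triangles[1, c(2, 1, 3)]
  expect_error(validate_mesh(flip), "oriented")
  expect_error(la_mesh(m$vertices, rbind(m$triangles, c(1L, 2L, 999L))),
               "out of range")
  expect_error(la_mesh(m$vertices, m$triangles, labels = "body"),
               "one entry per vertex")
})

test_that("boundary loops of a strip form one ordered cycle", {
  s <- strip_mesh(6, 3)
  loops <- boundary_loops(s$mesh$triangles)
  expect_length(loops, 1L)
  expect_setequal(loops[[1]],
                  which(s$x %in% c(0, 1) | s$y %in% c(0, 0.3)))
  # consecutive loop vertices share a mesh edge
  lp <- loops[[1]]
  e <- mesh_edges(s$mesh)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  nxt <- c(lp[-1], lp[1])
  expect_true(all(paste(pmin(lp, nxt), pmax(lp, nxt)) %in% key))
})

test_that("closed icosphere has no boundary", {
  expect_length(boundary_loops(icosphere(2)$triangles), 0L)
})

test_that("submesh re-indexes landmarks and labels consistently", {
  m <- icosphere(2, 5)
  m$labels[1:10] <- "LAA"
  m$landmarks <- list(probe = c(5L, 200L))
  sm <- submesh(m, seq_len(nrow(m$triangles) - 40L))
  expect_true(all(sm$mesh$triangles >= 1))
  expect_equal(m$labels[sm$vertex_map], sm$mesh$labels)
  expect_true(all(sm$vertex_map[sm$mesh$landmarks$probe] %in% c(5L, 200L)))
})
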