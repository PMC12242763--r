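# shared fixtures, generated in code and cached across test files

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# planar rectangular strip mesh on [0, 1] x [0, height]
strip_mesh <- function(nx = 11, ny = 4, height = 0.3) {
  xy <- expand.grid(x = seq(0, 1, length.out = nx),
                    y = seq(0, height, length.out = ny))
  v <- cbind(xy$x, xy$y, 0)
  idx <- function(i, j) (j - 1) * nx + i
  f <- NULL
  for (j in 1:(ny - 1)) for (i in 1:(nx - 1))
    f <- rbind(f, c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
               c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  list(mesh = la_mesh(v, f), x = xy$x, y = xy$y,
       left = which(xy$x == 0), right = which(xy$x == 1))
}

# test-scale generator settings: coarser mesh keeps the suite fast; the
# statistical structure is unchanged (see the methods vignette)
test_spec <- function(n, cohort, seed, ...) {
  cohort_spec(n, cohort, seed = seed, mesh_subdiv = 3L, ...)
}

af_cohort_47 <- function() fixture("af47", function()
  generate_cohort(test_spec(47, "AF", seed = 21)))

af_cohort_47b <- function() fixture("af47b", function()
  generate_cohort(test_spec(47, "AF", seed = 77)))

af_cohort_200 <- function() fixture("af200", function()
  generate_cohort(test_spec(200, "AF", seed = 31)))

healthy_cohort_200 <- function() fixture("healthy200", function()
  generate_cohort(test_spec(200, "healthy", seed = 32)))

small_af_cohort <- function() fixture("af8", function()
  generate_cohort(test_spec(8, "AF", seed = 41)))

small_healthy_cohort <- function() fixture("healthy8", function()
  generate_cohort(test_spec(8, "healthy", seed = 42)))

af_features_47 <- function() fixture("af47_ft", function()
  build_feature_table(analyze_cohort(af_cohort_47())))

clean_subject <- function() fixture("clean_subject", function()
  generate_subject(test_spec(1, "AF", seed = 1, intensity_noise_sd = 0,
                             motion_jitter_sd = 0), 31L, "A001"))

# independent all-pairs shortest-path oracle (Floyd-Warshall) on the mesh
# edge graph with Euclidean lengths
brute_geodesic <- function(mesh, seeds) {
  n <- nrow(mesh$vertices)
  e <- mesh_edges(mesh)
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (k in seq_len(nrow(e))) {
    d[e[k, 1], e[k, 2]] <- len[k]
    d[e[k, 2], e[k, 1]] <- len[k]
  }
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], "+")
    d <- pmin(d, dk)
  }
  apply(d[seeds, , drop = FALSE], 2, min)
}

# even-odd ray-casting volume oracle: fraction of grid cells whose centre
# ray (along +x) crosses the surface an odd number of times
raycast_volume <- function(vertices, triangles, h = 1.2) {
  lo <- apply(vertices, 2, min) - h
  hi <- apply(vertices, 2, max) + h
  ys <- seq(lo[2] + h / 2, hi[2], by = h)
  zs <- seq(lo[3] + h / 2, hi[3], by = h)
  v1 <- vertices[triangles[, 1], , drop = FALSE]
  v2 <- vertices[triangles[, 2], , drop = FALSE]
  v3 <- vertices[triangles[, 3], , drop = FALSE]
  inside_len <- 0
  for (y in ys) for (z in zs) {
    # 2D point-in-triangle test in the (y, z) projection
    d <- (v2[, 2] - v3[, 2]) * (v1[, 3] - v3[, 3]) +
      (v3[, 3] - v2[, 3]) * (v1[, 2] - v3[, 2])
    ok <- abs(d) > 1e-12
    a <- ((v2[, 2] - v3[, 2]) * (z - v3[, 3]) +
            (v3[, 3] - v2[, 3]) * (y - v3[, 2])) / d
    b <- ((v3[, 2] - v1[, 2]) * (z - v1[, 3]) +
            (v1[, 3] - v3[, 3]) * (y - v1[, 2])) / d
    cc <- 1 - a - b
    hit <- ok & a >= 0 & a <= 1 & b >= 0 & b <= 1 & cc >= 0 & cc <= 1
    if (!any(hit)) next
    # x-coordinates of the crossings
    xs <- a[hit] * v1[hit, 1] + b[hit] * v2[hit, 1] + cc[hit] * v3[hit, 1]
    xs <- sort(xs)
    if (length(xs) %% 2 == 0 && length(xs) > 0)
      inside_len <- inside_len + sum(xs[seq(2, length(xs), 2)] -
                                       xs[seq(1, length(xs), 2)])
  }
  inside_len * h * h / 1000   # mm^3 -> mL
}

# minimal feature table with subject-block structure for classifier tests
toy_table <- function(n_subjects = 30, seed = 1, p_severe = 0.5,
                      signal = 0) {
  set.seed(seed)
  lev <- la_regions()
  rows <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    sev <- stats::runif(6) < p_severe
    data.frame(subject = sprintf("S%03d", i),
               region = factor(lev, levels = lev),
               severe = sev,
               noise = stats::rnorm(6),
               sig = signal * sev + stats::rnorm(6))
  }))
  class(rows) <- c("feature_table", "data.frame")
  rows
}
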