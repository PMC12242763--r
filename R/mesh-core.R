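#' Labeled left-atrial surface mesh
#'
#' Constructs the package's core mesh container: a triangulated surface with
#' per-vertex anatomical labels and named landmark vertex sets. Positions are
#' in millimetres. Labels follow the LA convention used throughout:
#' `body`, `LAA`, `LSPV`, `LIPV`, `RSPV`, `RIPV`, `mitral_rim`.
#'
#' @param vertices numeric n x 3 matrix of vertex positions (mm).
#' @param triangles integer m x 3 matrix of 1-based vertex indices.
#' @param labels character vector of length n with one anatomical label per
#'   vertex. Defaults to `"body"` everywhere.
#' @param landmarks named list of integer vertex-index vectors (e.g. PV
#'   junction rings, septal/lateral anchors).
#' @param validate if `TRUE`, check manifoldness, connectivity, orientation
#'   consistency and positive triangle areas.
#' @return An object of class `la_mesh`.
#' @export
la_mesh <- function(vertices, triangles, labels = NULL, landmarks = list(),
                    validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  n <- nrow(vertices)
  if (any(triangles < 1L) || any(triangles > n))
    stop("triangle indices out of range")
  if (is.null(labels)) labels <- rep("body", n)
  if (length(labels) != n) stop("labels must have one entry per vertex")
  mesh <- structure(
    list(vertices = vertices, triangles = triangles,
         labels = as.character(labels), landmarks = landmarks),
    class = "la_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' @export
print.la_mesh <- function(x, ...) {
  cat("<la_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$triangles),
      " triangles\n", sep = "")
  tab <- table(x$labels)
  cat("  labels: ", paste(names(tab), tab, sep = ":", collapse = ", "), "\n",
      sep = "")
  if (length(x$landmarks))
    cat("  landmarks: ", paste(names(x$landmarks), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Validate mesh invariants
#'
#' Checks that the surface is a connected, consistently oriented 2-manifold
#' (each edge shared by at most two triangles, in opposite directions), and
#' that all triangle areas are strictly positive.
#'
#' @param mesh an [la_mesh].
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_mesh <- function(mesh) {
  tri <- mesh$triangles
  if (any(tri[, 1] == tri[, 2] | tri[, 2] == tri[, 3] | tri[, 1] == tri[, 3]))
    stop("degenerate triangle (repeated vertex index)")
  a <- triangle_areas(mesh)
  if (any(a <= 0) || any(!is.finite(a)))
    stop("all triangle areas must be > 0")
  he <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  key <- paste(he[, 1], he[, 2])
  if (anyDuplicated(key))
    stop("surface is not consistently oriented (duplicated half-edge)")
  ukey <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  cnt <- table(ukey)
  if (any(cnt > 2)) stop("non-manifold edge (shared by > 2 triangles)")
  g <- igraph::graph_from_edgelist(he, directed = FALSE)
  used <- sort(unique(as.vector(tri)))
  if (length(used) < nrow(mesh$vertices))
    stop("mesh contains unreferenced vertices")
  if (igraph::components(g)$no != 1L) stop("mesh is disconnected")
  invisible(TRUE)
}

#' Triangle areas of a surface mesh
#'
#' @param mesh an [la_mesh], or a vertex matrix if `triangles` is given.
#' @param triangles optional triangle index matrix.
#' @return numeric vector of areas in mm^2.
#' @export
triangle_areas <- function(mesh, triangles = NULL) {
  if (inherits(mesh, "la_mesh")) {
    v <- mesh$vertices; tri <- mesh$triangles
  } else {
    v <- mesh; tri <- triangles
  }
  e1 <- v[tri[, 2], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  e2 <- v[tri[, 3], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Per-triangle unit normals
#' @inheritParams triangle_areas
#' @return m x 3 matrix of unit normals.
#' @export
triangle_normals <- function(mesh, triangles = NULL) {
  if (inherits(mesh, "la_mesh")) {
    v <- mesh$vertices; tri <- mesh$triangles
  } else {
    v <- mesh; tri <- triangles
  }
  e1 <- v[tri[, 2], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  e2 <- v[tri[, 3], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / sqrt(rowSums(n^2))
}

#' Area-weighted outward vertex normals
#' @param mesh an [la_mesh].
#' @return n x 3 matrix of unit vertex normals.
#' @export
vertex_normals <- function(mesh) {
  tri <- mesh$triangles
  fn <- triangle_normals(mesh)
  fa <- triangle_areas(mesh)
  n <- matrix(0, nrow(mesh$vertices), 3)
  w <- fn * fa
  for (k in 1:3) {
    n[, 1] <- n[, 1] + tapply_add(tri[, k], w[, 1], nrow(n))
    n[, 2] <- n[, 2] + tapply_add(tri[, k], w[, 2], nrow(n))
    n[, 3] <- n[, 3] + tapply_add(tri[, k], w[, 3], nrow(n))
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# accumulate values into bins (vectorized scatter-add)
tapply_add <- function(idx, val, n) {
  out <- numeric(n)
  s <- rowsum(val, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Unique undirected edges of a mesh
#' @param mesh an [la_mesh].
#' @return two-column integer matrix, each row an edge with v1 < v2.
#' @export
mesh_edges <- function(mesh) {
  tri <- mesh$triangles
  he <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  e <- cbind(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  e[!duplicated(e), , drop = FALSE]
}

#' Boundary loops of an open surface
#'
#' Boundary edges are half-edges without an opposite partner. Returned loops
#' follow the orientation induced by the triangles.
#'
#' @param triangles triangle index matrix.
#' @return list of integer vectors, each an ordered closed loop of vertex
#'   indices.
#' @export
boundary_loops <- function(triangles) {
  he <- rbind(triangles[, 1:2], triangles[, 2:3], triangles[, c(3, 1)])
  key <- paste(he[, 1], he[, 2])
  rkey <- paste(he[, 2], he[, 1])
  isb <- !(key %in% rkey)
  be <- he[isb, , drop = FALSE]
  if (nrow(be) == 0L) return(list())
  # boundary loops run opposite to interior orientation; walk successor map
  nxt <- be[, 2]
  names(nxt) <- be[, 1]
  loops <- list()
  remaining <- stats::setNames(rep(TRUE, nrow(be)), be[, 1])
  starts <- be[, 1]
  visited <- character(0)
  for (s in starts) {
    s <- as.character(s)
    if (s %in% visited) next
    loop <- integer(0)
    cur <- s
    repeat {
      if (cur %in% visited) break
      visited <- c(visited, cur)
      loop <- c(loop, as.integer(cur))
      cur <- as.character(nxt[[cur]])
      if (cur == s) break
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Vertex adjacency list
#' @param mesh an [la_mesh].
#' @return list of integer neighbour vectors, one per vertex.
#' @export
vertex_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  adj <- split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]), levels = seq_len(n)))
  lapply(adj, as.integer)
}

#' Subdivided icosahedral sphere mesh
#'
#' Standard icosphere: recursively split each triangle into four and project
#' new vertices back to the sphere. Used as the base anatomy primitive and as
#' an analytic volume/strain fixture.
#'
#' @param subdiv number of subdivision rounds (0 = icosahedron).
#' @param radius sphere radius in mm.
#' @return an [la_mesh] with all vertices labelled `body`.
#' @export
icosphere <- function(subdiv = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      idx <- nv + length(newv)
      mid_cache[[key]] <- idx
      idx
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[(i - 1) * 4 + 1, ] <- c(a, ab, ca)
      nf[(i - 1) * 4 + 2, ] <- c(b, bc, ab)
      nf[(i - 1) * 4 + 3, ] <- c(c, ca, bc)
      nf[(i - 1) * 4 + 4, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  la_mesh(v * radius, f)
}

#' Extract a sub-mesh by triangle subset
#'
#' @param mesh an [la_mesh].
#' @param keep logical or integer triangle selector.
#' @return list with `mesh` (re-indexed, unvalidated) and `vertex_map`
#'   (old index for each new vertex).
#' @export
submesh <- function(mesh, keep) {
  tri <- mesh$triangles[keep, , drop = FALSE]
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  tri2 <- matrix(remap[tri], ncol = 3)
  lm <- lapply(mesh$landmarks, function(ix) {
    ix <- ix[ix %in% used]
    remap[ix]
  })
  m <- structure(list(vertices = mesh$vertices[used, , drop = FALSE],
                      triangles = tri2,
                      labels = mesh$labels[used],
                      landmarks = lm),
                 class = "la_mesh")
  list(mesh = m, vertex_map = used)
}
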