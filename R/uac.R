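#' Discrete harmonic field with Dirichlet boundary data
#'
#' Solves the Laplace equation on the mesh surface with a cotangent-weight
#' Laplacian and prescribed values on named vertex sets. Non-positive
#' cotangent edge weights (obtuse, poor-quality triangles) fall back to
#' uniform graph weights so the discrete maximum principle holds.
#'
#' @param mesh an [la_mesh]; must be connected.
#' @param boundary named list; each element is `list(vertices =, value =)`.
#'   Sets must be non-empty and pairwise disjoint.
#' @param tol solver tolerance used only for the residual check.
#' @return numeric vector, one value per vertex, with
#'   attribute `"boundary"` recording the Dirichlet sets.
#' @export
harmonic_field <- function(mesh, boundary, tol = 1e-10) {
  n <- nrow(mesh$vertices)
  if (!length(boundary)) stop("boundary sets must be non-empty")
  idx <- lapply(boundary, function(b) as.integer(b$vertices))
  if (any(lengths(idx) == 0L)) stop("boundary sets must be non-empty")
  all_b <- unlist(idx)
  if (anyDuplicated(all_b)) stop("boundary sets must not overlap")
  vals <- numeric(0)
  for (b in seq_along(boundary))
    vals <- c(vals, rep(boundary[[b]]$value, length(idx[[b]])))
  L <- cotan_laplacian(mesh)
  g <- igraph::graph_from_edgelist(mesh_edges(mesh), directed = FALSE)
  if (igraph::components(g)$no != 1L) stop("mesh is disconnected")
  x <- numeric(n)
  x[all_b] <- vals
  interior <- setdiff(seq_len(n), all_b)
  if (length(interior)) {
    Lii <- L[interior, interior, drop = FALSE]
    rhs <- -L[interior, all_b, drop = FALSE] %*% x[all_b]
    x[interior] <- as.numeric(Matrix::solve(Lii, rhs))
  }
  res <- max(abs(L[interior, , drop = FALSE] %*% x))
  attr(x, "boundary") <- boundary
  attr(x, "residual") <- res
  x
}

# cotangent-weight Laplacian (positive semi-definite convention: L x = 0 for
# constants; diagonal = sum of incident edge weights)
cotan_laplacian <- function(mesh) {
  v <- mesh$vertices
  tri <- mesh$triangles
  n <- nrow(v)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (k in 1:3) {
    a <- tri[, k]
    b <- tri[, (k %% 3) + 1]
    c <- tri[, ((k + 1) %% 3) + 1]
    # angle at c, opposite edge (a, b)
    u <- v[a, , drop = FALSE] - v[c, , drop = FALSE]
    w <- v[b, , drop = FALSE] - v[c, , drop = FALSE]
    cosang <- rowSums(u * w)
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    sinang <- sqrt(rowSums(cr^2))
    cot <- cosang / pmax(sinang, .Machine$double.eps)
    ii <- c(ii, a); jj <- c(jj, b); ww <- c(ww, cot / 2)
  }
  e1 <- pmin(ii, jj); e2 <- pmax(ii, jj)
  w <- rowsum(ww, paste(e1, e2))
  key <- rownames(w)
  parts <- matrix(as.integer(unlist(strsplit(key, " "))), ncol = 2, byrow = TRUE)
  wts <- w[, 1]
  bad <- wts < 0
  if (any(bad)) wts[bad] <- 1  # uniform graph-weight fallback
  i <- parts[, 1]; j <- parts[, 2]
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(wts, wts),
                            dims = c(n, n))
  Matrix::Diagonal(n, Matrix::rowSums(W)) - W
}

#' Universal-atrial-coordinate style parameterization
#'
#' Builds the two harmonic surface coordinates used for regionalization and
#' atlas transfer: `alpha` runs lateral (0) to septal (1), `beta` posterior
#' (0) to anterior (1). Dirichlet data come from named landmark sets; by
#' default the mesh landmarks `lateral_anchor`/`septal_anchor` and
#' `posterior_anchor`/`anterior_anchor` are used.
#'
#' @param mesh an [la_mesh].
#' @param boundary_spec optional list with elements `alpha` and `beta`, each
#'   a list of `list(vertices =, value =)` Dirichlet sets. Defaults to the
#'   mesh's anchor landmarks at values 0 and 1.
#' @return object of class `uac_field`: list with `alpha`, `beta` per-vertex
#'   vectors in \eqn{[0, 1]}.
#' @export
build_uac <- function(mesh, boundary_spec = NULL) {
  if (is.null(boundary_spec)) {
    lm <- mesh$landmarks
    need <- c("lateral_anchor", "septal_anchor",
              "posterior_anchor", "anterior_anchor")
    if (!all(need %in% names(lm)))
      stop("mesh lacks anchor landmarks; supply boundary_spec")
    boundary_spec <- list(
      alpha = list(list(vertices = lm$lateral_anchor, value = 0),
                   list(vertices = lm$septal_anchor, value = 1)),
      beta = list(list(vertices = lm$posterior_anchor, value = 0),
                  list(vertices = lm$anterior_anchor, value = 1)))
  }
  alpha <- harmonic_field(mesh, boundary_spec$alpha)
  beta <- harmonic_field(mesh, boundary_spec$beta)
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 residual = c(alpha = attr(alpha, "residual"),
                              beta = attr(beta, "residual"))),
            class = "uac_field")
}

#' @export
print.uac_field <- function(x, ...) {
  cat("<uac_field> alpha range [", signif(min(x$alpha), 3), ", ",
      signif(max(x$alpha), 3), "], beta range [", signif(min(x$beta), 3),
      ", ", signif(max(x$beta), 3), "]\n", sep = "")
  invisible(x)
}

#' Geodesic distance on the mesh edge graph
#'
#' Shortest-path distance over mesh edges with Euclidean edge lengths
#' (Dijkstra), from a seed vertex set to every vertex. This is the distance
#' used to delimit the PV antra.
#'
#' @param mesh an [la_mesh].
#' @param seeds integer vector of seed vertex indices.
#' @return numeric vector of distances in mm (0 on seeds).
#' @export
geodesic_distance <- function(mesh, seeds) {
  seeds <- as.integer(seeds)
  if (!length(seeds)) stop("seed set must be non-empty")
  e <- mesh_edges(mesh)
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  d <- igraph::distances(g, v = seeds, weights = len)
  apply(d, 2, min)
}

#' Six-region LA parcellation
#'
#' Assigns each `body` vertex to one of `LPVA`, `RPVA`, `posterior`,
#' `septal`, `anterior`, `lateral`. PV antra are the body vertices whose
#' geodesic distance to the left (right) PV junction rings is strictly less
#' than `antra_radius`; junction-ring vertices themselves belong to the
#' antrum. Remaining body vertices are split on the harmonic coordinates:
#' `beta < 1/3` posterior, `beta > 2/3` anterior, otherwise `alpha < 1/3`
#' lateral, `alpha > 2/3` septal, and the central roof band goes to
#' anterior/posterior at `beta >= 0.5`.
#'
#' @param mesh an [la_mesh] with junction-ring landmarks
#'   (`LSPV_junction`, `LIPV_junction`, `RSPV_junction`, `RIPV_junction`).
#' @param uac a [build_uac] result.
#' @param antra_radius antral geodesic radius in mm (default 10).
#' @param alpha_thresholds,beta_thresholds two-element cut points on the
#'   harmonic coordinates.
#' @return factor of length `nrow(vertices)` with the six region levels;
#'   `NA` for non-body vertices.
#' @export
assign_regions <- function(mesh, uac, antra_radius = 10,
                           alpha_thresholds = c(1 / 3, 2 / 3),
                           beta_thresholds = c(1 / 3, 2 / 3)) {
  stopifnot(antra_radius > 0)
  lm <- mesh$landmarks
  need <- c("LSPV_junction", "LIPV_junction", "RSPV_junction", "RIPV_junction")
  if (!all(need %in% names(lm)) || any(lengths(lm[need]) == 0L))
    stop("missing PV junction-ring landmarks")
  n <- nrow(mesh$vertices)
  body <- mesh$labels %in% c("body", "mitral_rim")
  dl <- geodesic_distance(mesh, c(lm$LSPV_junction, lm$LIPV_junction))
  dr <- geodesic_distance(mesh, c(lm$RSPV_junction, lm$RIPV_junction))
  region <- rep(NA_character_, n)
  in_l <- body & dl < antra_radius & dl <= dr
  in_r <- body & dr < antra_radius & dr < dl
  region[in_l] <- "LPVA"
  region[in_r] <- "RPVA"
  rest <- body & is.na(region)
  a <- uac$alpha; b <- uac$beta
  region[rest & b < beta_thresholds[1]] <- "posterior"
  region[rest & b > beta_thresholds[2]] <- "anterior"
  mid <- rest & is.na(region)
  region[mid & a < alpha_thresholds[1]] <- "lateral"
  region[mid & a > alpha_thresholds[2]] <- "septal"
  roof <- mid & is.na(region)
  region[roof] <- ifelse(b[roof] >= 0.5, "anterior", "posterior")
  factor(region, levels = la_regions())
}

#' Region level names
#' @return character vector of the six LA region names.
#' @export
la_regions <- function() {
  c("LPVA", "RPVA", "posterior", "septal", "anterior", "lateral")
}

#' Per-triangle region from vertex regions
#'
#' A triangle belongs to the majority region of its vertices (ties broken by
#' the first vertex's region); triangles with no labelled vertex get `NA`.
#'
#' @param mesh an [la_mesh].
#' @param regions factor from [assign_regions].
#' @return factor of length `nrow(triangles)`.
#' @export
triangle_regions <- function(mesh, regions) {
  tri <- mesh$triangles
  r <- matrix(as.integer(regions[tri]), ncol = 3)
  pick <- apply(r, 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_integer_)
    tb <- tabulate(x, nbins = 6L)
    m <- which(tb == max(tb))
    if (length(m) > 1L && x[1] %in% m) x[1] else m[1]
  })
  factor(la_regions()[pick], levels = la_regions())
}

#' Enclosed volume of a labelled surface
#'
#' Removes triangles touching excluded labels, caps every boundary loop
#' (mitral rim, excluded PV/LAA openings) with a flat fan lid at the loop
#' centroid, and evaluates the divergence-theorem volume of the closed,
#' consistently oriented surface.
#'
#' @param mesh an [la_mesh].
#' @param exclude character vector of vertex labels to exclude
#'   (default the LAA and the four PVs).
#' @return volume in mL.
#' @export
enclosed_volume <- function(mesh,
                            exclude = c("LAA", "LSPV", "LIPV", "RSPV", "RIPV")) {
  tri <- mesh$triangles
  if (length(exclude)) {
    ex <- mesh$labels %in% exclude
    keep <- !(ex[tri[, 1]] | ex[tri[, 2]] | ex[tri[, 3]])
  } else keep <- rep(TRUE, nrow(tri))
  if (!any(keep)) stop("no triangles left after exclusion")
  sm <- submesh(mesh, keep)
  capped <- cap_boundaries(sm$mesh)
  v <- capped$vertices; f <- capped$triangles
  he <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(he[, 1], he[, 2])
  if (anyDuplicated(key) || !all(paste(he[, 2], he[, 1]) %in% key))
    stop("surface is not closed/orientable after capping")
  v0 <- v[f[, 1], , drop = FALSE]
  v1 <- v[f[, 2], , drop = FALSE]
  v2 <- v[f[, 3], , drop = FALSE]
  det6 <- v0[, 1] * (v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2]) -
    v0[, 2] * (v1[, 1] * v2[, 3] - v1[, 3] * v2[, 1]) +
    v0[, 3] * (v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  abs(sum(det6)) / 6 / 1000  # mm^3 -> mL
}

# cap all boundary loops with a centroid fan; fan triangles oriented
# opposite to the boundary half-edges so the closed surface stays consistent
cap_boundaries <- function(mesh) {
  loops <- boundary_loops(mesh$triangles)
  v <- mesh$vertices
  f <- mesh$triangles
  for (lp in loops) {
    if (length(lp) < 3L) stop("degenerate boundary loop; surface not cappable")
    ctr <- colMeans(v[lp, , drop = FALSE])
    v <- rbind(v, ctr)
    ci <- nrow(v)
    nxt <- c(lp[-1], lp[1])
    f <- rbind(f, cbind(nxt, lp, ci))
  }
  list(vertices = v, triangles = f)
}

#' Map an atlas fibre field onto a target mesh via harmonic coordinates
#'
#' Each triangle's fibre vector is expressed in the local frame spanned by
#' the in-plane gradient of `alpha` and its in-plane orthogonal complement,
#' transferred to the target triangle nearest in `(alpha, beta)` space, and
#' rebuilt in the target triangle's own frame (hence tangent to it and of
#' unit norm).
#'
#' @param atlas_fibres m_atlas x 3 matrix of unit per-triangle fibre vectors
#'   on the atlas mesh.
#' @param atlas_mesh,atlas_uac atlas geometry and its [build_uac] field.
#' @param target_mesh,target_uac target geometry and field.
#' @return m_target x 3 matrix of unit tangent fibre vectors.
#' @export
map_fibres <- function(atlas_fibres, atlas_mesh, atlas_uac,
                       target_mesh, target_uac) {
  fa <- fibre_frames(atlas_mesh, atlas_uac)
  ft <- fibre_frames(target_mesh, target_uac)
  # decompose atlas fibres in local frames
  c1 <- rowSums(atlas_fibres * fa$e1)
  c2 <- rowSums(atlas_fibres * fa$e2)
  # nearest atlas triangle in (alpha, beta)
  au <- fa$uv; tu <- ft$uv
  nn <- nearest_rows(tu, au)
  f <- ft$e1 * c1[nn] + ft$e2 * c2[nn]
  len <- sqrt(rowSums(f^2))
  if (any(len < 1e-12)) stop("degenerate fibre after transfer")
  f / len
}

# per-triangle orthonormal tangent frame aligned to grad(alpha), plus the
# triangle's (alpha, beta) barycentre
fibre_frames <- function(mesh, uac) {
  v <- mesh$vertices; tri <- mesh$triangles
  n <- triangle_normals(mesh)
  ga <- triangle_gradient(mesh, uac$alpha)
  # fall back to an arbitrary tangent where grad alpha vanishes
  glen <- sqrt(rowSums(ga^2))
  weak <- glen < 1e-12
  if (any(weak)) {
    e <- v[tri[weak, 2], , drop = FALSE] - v[tri[weak, 1], , drop = FALSE]
    ga[weak, ] <- e
    glen[weak] <- sqrt(rowSums(ga[weak, , drop = FALSE]^2))
  }
  e1 <- ga / glen
  e2 <- cbind(n[, 2] * e1[, 3] - n[, 3] * e1[, 2],
              n[, 3] * e1[, 1] - n[, 1] * e1[, 3],
              n[, 1] * e1[, 2] - n[, 2] * e1[, 1])
  uv <- cbind(rowMeans(matrix(uac$alpha[tri], ncol = 3)),
              rowMeans(matrix(uac$beta[tri], ncol = 3)))
  list(e1 = e1, e2 = e2, uv = uv)
}

# in-plane gradient of a per-vertex scalar on each triangle
triangle_gradient <- function(mesh, x) {
  v <- mesh$vertices; tri <- mesh$triangles
  p0 <- v[tri[, 1], , drop = FALSE]
  e1 <- v[tri[, 2], , drop = FALSE] - p0
  e2 <- v[tri[, 3], , drop = FALSE] - p0
  d1 <- x[tri[, 2]] - x[tri[, 1]]
  d2 <- x[tri[, 3]] - x[tri[, 1]]
  # solve 2x2 metric system per triangle
  g11 <- rowSums(e1 * e1); g12 <- rowSums(e1 * e2); g22 <- rowSums(e2 * e2)
  det <- g11 * g22 - g12^2
  det[det == 0] <- .Machine$double.eps
  a <- (g22 * d1 - g12 * d2) / det
  b <- (g11 * d2 - g12 * d1) / det
  e1 * a + e2 * b
}

# index of nearest row of `ref` for each row of `x` (brute force, chunked)
nearest_rows <- function(x, ref, chunk = 2048L) {
  n <- nrow(x)
  out <- integer(n)
  r2 <- rowSums(ref^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    xx <- x[s:e, , drop = FALSE]
    d <- outer(rowSums(xx^2), r2, "+") - 2 * xx %*% t(ref)
    out[s:e] <- max.col(-d, ties.method = "first")
  }
  out
}
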