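#' Write a mesh as legacy ASCII VTK polydata
#'
#' Vertex labels and any per-vertex fields go to POINT_DATA; per-triangle
#' vector fields (e.g. fibres) go to CELL_DATA. Landmarks are written as a
#' sidecar JSON file (`<path>.landmarks.json`) with 1-based indices.
#'
#' @param mesh an [la_mesh].
#' @param path output file path (conventionally `.vtk`).
#' @param point_data named list of numeric per-vertex vectors.
#' @param cell_data named list of per-triangle vectors (length m) or m x 3
#'   matrices (written as VECTORS).
#' @param landmarks_sidecar write `<path>.landmarks.json`? Default `TRUE`
#'   when the mesh has landmarks.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list(),
                      landmarks_sidecar = length(mesh$landmarks) > 0) {
  v <- mesh$vertices; f <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "la_mesh surface", "ASCII", "DATASET POLYDATA"), con)
  writeLines(sprintf("POINTS %d double", nrow(v)), con)
  writeLines(paste(format(v[, 1], digits = 17), format(v[, 2], digits = 17),
                   format(v[, 3], digits = 17)), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), nrow(f) * 4L), con)
  writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  labs <- unique(mesh$labels)
  writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
  writeLines("SCALARS label int 1", con)
  writeLines("LOOKUP_TABLE default", con)
  writeLines(as.character(match(mesh$labels, labs) - 1L), con)
  for (nm in names(point_data)) {
    x <- point_data[[nm]]
    writeLines(sprintf("SCALARS %s double 1", nm), con)
    writeLines("LOOKUP_TABLE default", con)
    writeLines(format(as.numeric(x), digits = 17), con)
  }
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", nrow(f)), con)
    for (nm in names(cell_data)) {
      x <- cell_data[[nm]]
      if (is.matrix(x) && ncol(x) == 3L) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(paste(format(x[, 1], digits = 17),
                         format(x[, 2], digits = 17),
                         format(x[, 3], digits = 17)), con)
      } else {
        writeLines(sprintf("SCALARS %s double 1", nm), con)
        writeLines("LOOKUP_TABLE default", con)
        writeLines(format(as.numeric(x), digits = 17), con)
      }
    }
  }
  # label dictionary as trailing comment-free FIELD
  writeLines(sprintf("FIELD label_names 1"), con)
  writeLines(sprintf("label_dictionary %d 1 string", length(labs)), con)
  writeLines(labs, con)
  if (landmarks_sidecar)
    jsonlite::write_json(mesh$landmarks, paste0(path, ".landmarks.json"))
  invisible(path)
}

#' Read a mesh written by [write_vtk]
#'
#' Supports the subset of legacy ASCII VTK polydata this package writes:
#' POINTS, POLYGONS (triangles), POINT_DATA scalars, CELL_DATA
#' scalars/vectors, and the label dictionary FIELD. Landmark sidecar JSON is
#' read back when present.
#'
#' @param path a `.vtk` file.
#' @return an [la_mesh]; extra per-vertex fields are attached as the
#'   `point_data` attribute, per-cell fields as `cell_data`.
#' @export
read_vtk <- function(path) {
  ln <- readLines(path)
  ip <- grep("^POINTS ", ln)[1]
  np <- as.integer(strsplit(ln[ip], " ")[[1]][2])
  pts <- scan(text = ln[(ip + 1):(ip + np)], quiet = TRUE)
  v <- matrix(pts, ncol = 3, byrow = TRUE)
  ig <- grep("^POLYGONS ", ln)[1]
  nf <- as.integer(strsplit(ln[ig], " ")[[1]][2])
  fv <- scan(text = ln[(ig + 1):(ig + nf)], quiet = TRUE)
  fm <- matrix(fv, ncol = 4, byrow = TRUE)
  if (any(fm[, 1] != 3L)) stop("non-triangle polygon in VTK file")
  f <- fm[, 2:4, drop = FALSE] + 1L
  point_data <- list(); cell_data <- list()
  labels <- rep("body", np)
  sc <- grep("^SCALARS |^VECTORS ", ln)
  cd_start <- grep("^CELL_DATA ", ln)
  cd_start <- if (length(cd_start)) cd_start[1] else Inf
  lab_idx <- NULL
  for (i in sc) {
    parts <- strsplit(ln[i], " ")[[1]]
    nm <- parts[2]
    is_cell <- i > cd_start
    nvals <- if (is_cell) nf else np
    if (parts[1] == "VECTORS") {
      vals <- scan(text = ln[(i + 1):(i + nvals)], quiet = TRUE)
      cell_data[[nm]] <- matrix(vals, ncol = 3, byrow = TRUE)
    } else {
      vals <- scan(text = ln[(i + 2):(i + 1 + nvals)], quiet = TRUE)
      if (nm == "label" && !is_cell) lab_idx <- as.integer(vals)
      else if (is_cell) cell_data[[nm]] <- vals
      else point_data[[nm]] <- vals
    }
  }
  fd <- grep("^label_dictionary ", ln)
  if (length(fd) && !is.null(lab_idx)) {
    nl <- as.integer(strsplit(ln[fd[1]], " ")[[1]][2])
    dict <- ln[(fd[1] + 1):(fd[1] + nl)]
    labels <- dict[lab_idx + 1L]
  }
  lmf <- paste0(path, ".landmarks.json")
  landmarks <- if (file.exists(lmf)) {
    lapply(jsonlite::read_json(lmf), function(x) as.integer(unlist(x)))
  } else list()
  mesh <- la_mesh(v, f, labels, landmarks, validate = FALSE)
  attr(mesh, "point_data") <- point_data
  attr(mesh, "cell_data") <- cell_data
  mesh
}

#' Write a mesh as ASCII PLY
#' @param mesh an [la_mesh].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(paste(format(v[, 1], digits = 17), format(v[, 2], digits = 17),
                   format(v[, 3], digits = 17)), con)
  writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY triangle mesh
#' @param path a `.ply` file.
#' @return an [la_mesh] with default labels.
#' @export
read_ply <- function(path) {
  ln <- readLines(path)
  endh <- grep("^end_header", ln)[1]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", ln, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face ", ln, value = TRUE)[1]))
  pts <- scan(text = ln[(endh + 1):(endh + nv)], quiet = TRUE)
  v <- matrix(pts, ncol = 3, byrow = TRUE)
  fv <- scan(text = ln[(endh + nv + 1):(endh + nv + nf)], quiet = TRUE)
  fm <- matrix(fv, ncol = 4, byrow = TRUE)
  la_mesh(v, fm[, 2:4, drop = FALSE] + 1L, validate = FALSE)
}

#' Write a mesh motion sequence as a VTK file series
#'
#' One VTK file per frame plus a JSON manifest with frame times.
#'
#' @param motion a [mesh_motion].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return the manifest path, invisibly.
#' @export
write_motion <- function(motion, dir, prefix = "frame") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- motion$reference
  files <- character(length(motion$frames))
  for (i in seq_along(motion$frames)) {
    m <- ref
    m$vertices <- motion$frames[[i]]
    files[i] <- file.path(dir, sprintf("%s_%03d.vtk", prefix, i - 1L))
    write_vtk(m, files[i], landmarks_sidecar = (i == 1L))
  }
  manifest <- file.path(dir, paste0(prefix, "_times.json"))
  jsonlite::write_json(list(files = basename(files),
                            frame_times = motion$frame_times),
                       manifest, auto_unbox = FALSE, digits = NA)
  invisible(manifest)
}

#' Read a mesh motion sequence written by [write_motion]
#' @param manifest the `_times.json` manifest path.
#' @return a [mesh_motion].
#' @export
read_motion <- function(manifest) {
  info <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  meshes <- lapply(file.path(dir, info$files), read_vtk)
  ref <- meshes[[1]]
  mesh_motion(ref, lapply(meshes, function(m) m$vertices),
              frame_times = info$frame_times)
}
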