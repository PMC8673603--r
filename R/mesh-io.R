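#' Triangle mesh of a tooth crown
#'
#' The basic container for all geometric measurements: an indexed triangle
#' mesh in millimetres. Vertices are stored as an `n x 3` numeric matrix and
#' faces as an `m x 3` integer matrix of 1-based vertex indices (file formats
#' and the annotation CSV interface are 0-based; conversion happens at I/O).
#' Faces are assumed counter-clockwise when seen from outside/above, so face
#' normals point outward for closed meshes and occlusally (+z) for crown
#' height fields in the occlusal frame.
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z) in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param clean logical; merge coincident vertices (within `merge_tol`) and
#'   drop degenerate (zero-area) faces before validation.
#' @param merge_tol vertex merge tolerance in mm.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, clean = TRUE, merge_tol = 1e-6) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns", call. = FALSE)
  if (ncol(faces) != 3L) stop("faces must have 3 columns", call. = FALSE)
  if (nrow(faces) < 1L) stop("mesh must have at least one face", call. = FALSE)
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range", call. = FALSE)
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "triangle_mesh")
  if (clean) mesh <- clean_mesh(mesh, merge_tol = merge_tol)
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2L, range)
  cat(sprintf("  bbox [mm]: x %.3f..%.3f  y %.3f..%.3f  z %.3f..%.3f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# Merge vertices closer than merge_tol and drop zero-area / repeated-index
# faces. Scanner exports are dirty; downstream math assumes non-degenerate
# triangles. Reports what was removed via message().
clean_mesh <- function(mesh, merge_tol = 1e-6, quiet = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  key <- apply(round(v / merge_tol), 1L, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  n_merged <- nrow(v) - sum(first)
  v2 <- v[first, , drop = FALSE]
  f2 <- matrix(map[f], ncol = 3L)
  repeated <- f2[, 1] == f2[, 2] | f2[, 2] == f2[, 3] | f2[, 1] == f2[, 3]
  a <- triangle_areas(v2, f2)
  degenerate <- repeated | a <= .Machine$double.eps * 100
  n_dropped <- sum(degenerate)
  f2 <- f2[!degenerate, , drop = FALSE]
  if (nrow(f2) == 0L) stop("mesh empty after cleaning", call. = FALSE)
  used <- sort(unique(as.vector(f2)))
  remap <- integer(nrow(v2)); remap[used] <- seq_along(used)
  out <- structure(list(vertices = v2[used, , drop = FALSE],
                        faces = matrix(remap[f2], ncol = 3L)),
                   class = "triangle_mesh")
  if (!quiet && (n_merged > 0L || n_dropped > 0L))
    message(sprintf("mesh cleaning: merged %d vertices, dropped %d degenerate faces",
                    n_merged, n_dropped))
  out
}

# per-face areas for raw vertex/face matrices
triangle_areas <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# per-face unit normals (CCW convention); degenerate faces are excluded at load
face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / sqrt(rowSums(n^2))
}

face_centroids <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

#' Read a triangle mesh from STL, PLY or OBJ
#'
#' Reads ASCII or binary STL, ASCII PLY, or Wavefront OBJ. The format is
#' auto-detected from the file extension unless given. The mesh is cleaned on
#' load: coincident vertices merged (1e-6 mm) and degenerate faces dropped,
#' with counts reported.
#'
#' @param path file path.
#' @param format one of `"stl"`, `"ply"`, `"obj"`; default from extension.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  switch(tolower(format),
         stl = read_stl(path),
         ply = read_ply(path),
         obj = read_obj(path),
         stop("unsupported mesh format: ", format, call. = FALSE))
}

#' Write a triangle mesh
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param format `"stl"` (ASCII), `"stl_binary"`, `"ply"` or `"obj"`; default
#'   from extension (STL written ASCII).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  switch(tolower(format),
         stl = write_stl_ascii(mesh, path),
         stl_binary = write_stl_binary(mesh, path),
         ply = write_ply(mesh, path),
         obj = write_obj(mesh, path),
         stop("unsupported mesh format: ", format, call. = FALSE))
  invisible(path)
}

is_binary_stl <- function(path) {
  sz <- file.size(path)
  if (sz < 84) return(FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  header <- readBin(con, "raw", 80L)
  n_tri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  # binary STL size is exactly 84 + 50 * n_tri; ASCII files start with "solid"
  # but so may binary headers, so trust the size identity first
  if (!is.na(n_tri) && sz == 84 + 50 * as.numeric(n_tri)) return(TRUE)
  !identical(rawToChar(header[1:5]), "solid")
}

read_stl <- function(path) {
  if (is_binary_stl(path)) {
    con <- file(path, "rb"); on.exit(close(con))
    readBin(con, "raw", 80L)
    n_tri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    tri <- matrix(NA_real_, n_tri * 3L, 3L)
    for (i in seq_len(n_tri)) {
      vals <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
      tri[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
      readBin(con, "raw", 2L)
    }
  } else {
    txt <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vlines) == 0L || length(vlines) %% 3L != 0L)
      stop("malformed ASCII STL: ", path, call. = FALSE)
    tri <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(p)
      as.numeric(p[2:4])))
  }
  n_tri <- nrow(tri) / 3L
  faces <- matrix(seq_len(3L * n_tri), ncol = 3L, byrow = TRUE)
  triangle_mesh(tri, faces)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  nrm <- face_normals(mesh)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("solid mesh", con)
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                       nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
    writeLines("    outer loop", con)
    for (k in 1:3) {
      p <- v[f[i, k], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
    }
    writeLines(c("    endloop", "  endfacet"), con)
  }
  writeLines("endsolid mesh", con)
}

write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  nrm <- face_normals(mesh)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(raw(80L), con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(f))) {
    vals <- c(nrm[i, ], t(v[f[i, ], , drop = FALSE]))
    writeBin(as.numeric(vals), con, size = 4L, endian = "little")
    writeBin(as.integer(0L), con, size = 2L, endian = "little")
  }
}

read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (!grepl("^ply", txt[1])) stop("not a PLY file: ", path, call. = FALSE)
  if (!any(grepl("format\\s+ascii", txt)))
    stop("only ASCII PLY is supported", call. = FALSE)
  end_header <- grep("^end_header", txt)[1]
  nv <- as.integer(sub(".*element\\s+vertex\\s+(\\d+).*", "\\1",
                       grep("element\\s+vertex", txt, value = TRUE)[1]))
  nf <- as.integer(sub(".*element\\s+face\\s+(\\d+).*", "\\1",
                       grep("element\\s+face", txt, value = TRUE)[1]))
  body <- txt[(end_header + 1L):length(txt)]
  vv <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                              function(p) as.numeric(p[1:3])))
  ff <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                              function(p) {
                                p <- as.integer(p)
                                if (p[1] != 3L) stop("non-triangular PLY face", call. = FALSE)
                                p[2:4] + 1L
                              }))
  triangle_mesh(vv, ff)
}

write_ply <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
}

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", txt, value = TRUE)
  flines <- grep("^f\\s", txt, value = TRUE)
  if (length(vlines) == 0L || length(flines) == 0L)
    stop("malformed OBJ: ", path, call. = FALSE)
  vv <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                              function(p) as.numeric(p[2:4])))
  ff <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), function(p) {
    idx <- as.integer(sub("/.*", "", p[-1]))
    if (length(idx) != 3L) stop("non-triangular OBJ face", call. = FALSE)
    idx
  }))
  triangle_mesh(vv, ff)
}

write_obj <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
}

# rigid (or affine) transform of a mesh by a 4x4 matrix
transform_mesh <- function(mesh, tf) {
  stopifnot(all(dim(tf) == c(4L, 4L)))
  v <- cbind(mesh$vertices, 1) %*% t(tf)
  structure(list(vertices = v[, 1:3, drop = FALSE], faces = mesh$faces),
            class = "triangle_mesh")
}

translate_mesh <- function(mesh, offset) {
  structure(list(vertices = sweep(mesh$vertices, 2L, offset, "+"),
                 faces = mesh$faces), class = "triangle_mesh")
}
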