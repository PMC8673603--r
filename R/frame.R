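#' Cervical band selection
#'
#' The cervical reference plane is fitted to mesh vertices lying within
#' `half_width` (default 0.2 mm) orthogonal distance of the best-fit plane of
#' a user-supplied polyline drawn around the tooth cervix, mirroring the
#' select-0.2mm-above-and-below workflow of metrology software.
#'
#' @param mesh a [triangle_mesh()].
#' @param polyline numeric matrix of 3D points tracing the cervix.
#' @param half_width band half-width in mm (> 0).
#' @return object of class `cervical_band` with fields `polyline`,
#'   `half_width`, `vertex_ids` (1-based mesh vertex indices).
#' @export
cervical_band <- function(mesh, polyline, half_width = 0.2) {
  stopifnot(inherits(mesh, "triangle_mesh"), half_width > 0)
  pl <- fit_plane(as.matrix(polyline))
  d <- plane_distance(pl, mesh$vertices)
  ids <- which(abs(d) <= half_width)
  if (length(ids) == 0L)
    stop("no mesh vertices within the cervical band", call. = FALSE)
  structure(list(polyline = as.matrix(polyline), half_width = half_width,
                 vertex_ids = ids),
            class = "cervical_band")
}

#' Occlusal coordinate frame
#'
#' Orthonormal right-handed frame with z = cervical-plane normal pointing
#' occlusally, x = mesio-distal direction projected into the plane.
#'
#' @param origin 3-vector.
#' @param zaxis,xaxis 3-vectors; `xaxis` is orthogonalised against `zaxis`.
#' @return object of class `occlusal_frame` with fields `origin` and
#'   `rotation` (columns = frame axes in world coordinates).
#' @export
occlusal_frame <- function(origin, zaxis, xaxis) {
  z <- zaxis / sqrt(sum(zaxis^2))
  x <- xaxis - sum(xaxis * z) * z
  nx <- sqrt(sum(x^2))
  if (nx < 1e-9)
    stop("mesio-distal hint is parallel to the cervical normal", call. = FALSE)
  x <- x / nx
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  structure(list(origin = as.numeric(origin), rotation = cbind(x, y, z)),
            class = "occlusal_frame")
}

#' Align a crown mesh to its occlusal coordinate frame
#'
#' Fits the cervical reference plane to the band vertices, orients its normal
#' toward the occlusal side (the mesh bulk), and rigidly moves the mesh so the
#' cervical plane is z = 0, occlusal is +z and the mesio-distal hint is the
#' +x axis.
#'
#' @param mesh a [triangle_mesh()].
#' @param band a [cervical_band()] for `mesh`.
#' @param mesiodistal_hint non-zero 3-vector, not parallel to the cervical
#'   normal.
#' @return list with `mesh` (transformed), `transform` (4x4 world-to-frame),
#'   `frame` (the [occlusal_frame()]) and `cervical_plane` (the fitted
#'   [plane3d()] in original coordinates).
#' @export
align_to_occlusal_frame <- function(mesh, band, mesiodistal_hint = c(1, 0, 0)) {
  stopifnot(inherits(band, "cervical_band"))
  pts <- mesh$vertices[band$vertex_ids, , drop = FALSE]
  pl <- fit_plane(pts)
  # occlusal side = side holding the mesh bulk (crown rises away from cervix)
  bulk <- colMeans(mesh$vertices)
  if (plane_distance(pl, rbind(bulk)) < 0) pl <- plane3d(-pl$normal, -pl$offset)
  origin <- colMeans(pts)
  origin <- origin - plane_distance(pl, rbind(origin))[1] * pl$normal
  fr <- occlusal_frame(origin, pl$normal, as.numeric(mesiodistal_hint))
  tf <- frame_transform(fr)
  list(mesh = transform_mesh(mesh, tf), transform = tf, frame = fr,
       cervical_plane = pl)
}

# 4x4 world-to-frame rigid transform from an occlusal_frame
frame_transform <- function(frame) {
  R <- t(frame$rotation)
  tf <- diag(4)
  tf[1:3, 1:3] <- R
  tf[1:3, 4] <- -as.numeric(R %*% frame$origin)
  tf
}

#' Serialize / read a 4x4 transform as row-major JSON
#' @param tf 4x4 matrix.
#' @param path output path.
#' @return `path` invisibly (`write`), or the 4x4 matrix (`read`).
#' @export
write_transform_json <- function(tf, path) {
  stopifnot(all(dim(tf) == c(4L, 4L)))
  jsonlite::write_json(list(rows = apply(tf, 1L, function(r) r, simplify = FALSE)),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- obj$rows
  if (is.list(m)) m <- do.call(rbind, lapply(m, as.numeric))
  m <- matrix(as.numeric(m), 4L, 4L)
  m
}
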