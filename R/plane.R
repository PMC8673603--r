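#' Plane in Hessian normal form
#'
#' `normal %*% x == offset` for points x on the plane; `normal` is unit length.
#' Houses both the cervical reference plane and per-facet best-fit planes.
#'
#' @param normal 3-vector, normalised internally.
#' @param offset signed offset (mm).
#' @return an object of class `plane3d`.
#' @export
plane3d <- function(normal, offset) {
  normal <- as.numeric(normal)
  nn <- sqrt(sum(normal^2))
  if (!is.finite(nn) || nn < 1e-12) stop("zero-length plane normal", call. = FALSE)
  structure(list(normal = normal / nn, offset = as.numeric(offset) / nn),
            class = "plane3d")
}

#' @export
print.plane3d <- function(x, ...) {
  cat(sprintf("plane3d: normal (%.6f, %.6f, %.6f), offset %.6f mm\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  invisible(x)
}

plane_distance <- function(plane, points) {
  as.numeric(points %*% plane$normal - plane$offset)
}

#' Total-least-squares (gaussian best-fit) plane
#'
#' Fits the plane minimising the sum of squared orthogonal distances, via
#' eigen-decomposition of the point covariance: the normal is the eigenvector
#' of the smallest eigenvalue. This is the standard metrology meaning of a
#' "gaussian best-fit" plane.
#'
#' @param points numeric matrix of 3D points (rows).
#' @param orient optional reference direction; the normal is flipped so its
#'   dot product with `orient` is positive (default +z).
#' @return a [plane3d()].
#' @export
fit_plane <- function(points, orient = c(0, 0, 1)) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("need at least 3 points to fit a plane", call. = FALSE)
  ctr <- colMeans(points)
  x <- sweep(points, 2L, ctr)
  e <- eigen(crossprod(x) / nrow(x), symmetric = TRUE)
  # collinear points: the two smallest eigenvalues both ~ 0 relative to spread
  if (e$values[2] <= max(e$values[1], 1) * 1e-12)
    stop("points are collinear; plane is not defined", call. = FALSE)
  n <- e$vectors[, 3]
  if (sum(n * orient) < 0) n <- -n
  plane3d(n, sum(n * ctr))
}

#' Angle between two planes, folded to [0, 90] degrees
#'
#' The dip angle of a wear facet is this angle between the facet's best-fit
#' plane and the cervical reference plane.
#'
#' @param a,b [plane3d()] objects.
#' @return angle in degrees.
#' @export
plane_angle <- function(a, b) {
  ca <- abs(sum(a$normal * b$normal))
  acos(min(1, max(-1, ca))) * 180 / pi
}
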