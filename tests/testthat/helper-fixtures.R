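# Geometric fixtures built in code; shared across test files.

# Unit cube [0,1]^3, 12 CCW-outward triangles.
unit_cube <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # faces as 1-based indices into the expand.grid order
  f <- rbind(
    c(1, 5, 7), c(1, 7, 3),   # x = 0 (normal -x)
    c(2, 4, 8), c(2, 8, 6),   # x = 1 (+x)
    c(1, 2, 6), c(1, 6, 5),   # y = 0 (-y)
    c(3, 7, 8), c(3, 8, 4),   # y = 1 (+y)
    c(1, 3, 4), c(1, 4, 2),   # z = 0 (-z)
    c(5, 6, 8), c(5, 8, 7))   # z = 1 (+z)
  triangle_mesh(v, f, clean = FALSE)
}

# Unit square plate in z = z0, 2 triangles, +z normals, optional grid refinement.
unit_plate <- function(z0 = 0, n = 1L) {
  g <- seq(0, 1, length.out = n + 1L)
  gx <- rep(g, times = n + 1L)
  gy <- rep(g, each = n + 1L)
  vid <- function(ix, iy) (iy - 1L) * (n + 1L) + ix
  ix <- rep(seq_len(n), times = n); iy <- rep(seq_len(n), each = n)
  a <- vid(ix, iy); b <- vid(ix + 1L, iy); c <- vid(ix, iy + 1L)
  d <- vid(ix + 1L, iy + 1L)
  triangle_mesh(cbind(gx, gy, z0), rbind(cbind(a, b, d), cbind(a, d, c)),
                clean = FALSE)
}

# plate with -z normals (occluding surface of an "upper" tooth)
unit_plate_down <- function(z0 = 0, n = 1L) {
  m <- unit_plate(z0, n)
  triangle_mesh(m$vertices, m$faces[, c(1, 3, 2)], clean = FALSE)
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3L, 3L,
              byrow = TRUE)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

rigid_transform_mesh <- function(mesh, R, t = c(0, 0, 0)) {
  triangle_mesh(sweep(mesh$vertices %*% t(R), 2L, t, "+"), mesh$faces,
                clean = FALSE)
}

# small molar used by several files (coarser than the package default)
test_molar <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_synthetic_molar(molar_spec(resolution = 100L))
    cache
  }
})

skip_if_no_vegan <- function() {
  # vegan is part of the pinned environment; this guard exists only so the
  # failure mode is a clear message rather than a missing-namespace error
  if (!requireNamespace("vegan", quietly = TRUE))
    stop("vegan is required for the oracle tests but is not installed")
}
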