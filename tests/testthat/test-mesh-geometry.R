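test_that("STL round-trips in ASCII and binary with vertex merging", {
  cube <- unit_cube()
  fa <- tempfile(fileext = ".stl")
  fb <- tempfile(fileext = ".stl")
  write_mesh(cube, fa)                      # ASCII
  write_mesh(cube, fb, format = "stl_binary")
  for (f in c(fa, fb)) {
    m <- read_mesh(f)
    expect_equal(nrow(m$vertices), 8L)
    expect_equal(nrow(m$faces), 12L)
    expect_equal(surface_area(m), 6, tolerance = 1e-6)
  }
})

test_that("PLY and OBJ round-trip", {
  cube <- unit_cube()
  for (ext in c("ply", "obj")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_mesh(cube, f)
    m <- read_mesh(f)
    expect_equal(nrow(m$vertices), 8L)
    expect_equal(sort(as.vector(m$vertices)), sort(as.vector(cube$vertices)),
                 tolerance = 1e-6)
    expect_equal(surface_area(m), 6, tolerance = 1e-6)
  }
})

test_that("degenerate faces are dropped with a message at load", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0))
  f <- rbind(c(1, 2, 3),   # collinear
             c(1, 2, 4))
  expect_message(m <- triangle_mesh(v, f), "dropped 1 degenerate")
  expect_equal(nrow(m$faces), 1L)
  expect_error(triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                             rbind(c(1, 2, 3))),
               "empty")
})

test_that("fit_plane recovers exact and analytic planes", {
  set.seed(11)
  pts <- cbind(runif(50), runif(50), 2)
  pl <- fit_plane(pts)
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(pl$offset, 2, tolerance = 1e-9)

  # points on z = x * tan(20 deg): dip angle downstream is 20 degrees
  x <- runif(100, -1, 1); y <- runif(100, -1, 1)
  pl2 <- fit_plane(cbind(x, y, x * tan(20 * pi / 180)))
  expect_equal(plane_angle(pl2, plane3d(c(0, 0, 1), 0)), 20, tolerance = 1e-6)

  expect_error(fit_plane(cbind(1:5, 2 * (1:5), 3 * (1:5))), "collinear")
  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 1, 1))), "3 points")
})

test_that("fit_plane matches an independent SVD oracle on noisy points", {
  set.seed(42)
  pts <- cbind(runif(500, -1, 1), runif(500, -1, 1), rnorm(500, sd = 0.01))
  pl <- fit_plane(pts)
  # oracle: right-singular vector of the centred point matrix
  x <- sweep(pts, 2L, colMeans(pts))
  n_svd <- svd(x)$v[, 3]
  if (n_svd[3] < 0) n_svd <- -n_svd
  expect_equal(pl$normal, n_svd, tolerance = 1e-9)
  expect_lt(plane_angle(pl, plane3d(c(0, 0, 1), 0)), 0.5)
})

test_that("fit_plane is invariant to rigid transforms", {
  set.seed(7)
  pts <- cbind(runif(60), runif(60), 0.3 * runif(60))
  pl <- fit_plane(pts)
  for (k in 1:5) {
    R <- rotation_matrix(rnorm(3), runif(1, 0, pi))
    t <- rnorm(3)
    pl2 <- fit_plane(sweep(pts %*% t(R), 2L, t, "+"), orient = R %*% pl$normal)
    expect_equal(as.numeric(pl2$normal), as.numeric(R %*% pl$normal),
                 tolerance = 1e-8)
    # transformed plane passes through transformed centroid
    ctr2 <- as.numeric(R %*% colMeans(pts)) + t
    expect_equal(sum(pl2$normal * ctr2) - pl2$offset, 0, tolerance = 1e-8)
  }
})

test_that("surface_area: analytic values, additivity, rigid invariance", {
  expect_equal(surface_area(unit_plate()), 1)
  cube <- unit_cube()
  expect_equal(surface_area(cube), 6)
  # fine hemisphere approaches 2*pi*r^2
  h <- make_primitive("hemisphere", list(radius = 1, resolution = 128L))
  expect_equal(surface_area(h), 2 * pi, tolerance = 2e-3)

  idx <- seq_len(nrow(cube$faces))
  split <- sample(idx, 5)
  expect_equal(surface_area(cube, split) + surface_area(cube, setdiff(idx, split)),
               surface_area(cube))
  R <- rotation_matrix(c(1, 2, 3), 1.1)
  expect_equal(surface_area(rigid_transform_mesh(cube, R, c(5, -2, 1))), 6,
               tolerance = 1e-9)
  expect_error(surface_area(cube, 13L), "invalid face index")
})

test_that("cross_section_at_plane: cube, hemisphere, cone", {
  cube <- unit_cube()
  cs <- cross_section_at_plane(cube, plane3d(c(0, 0, 1), 0.5))
  expect_equal(cs$area2d, 1, tolerance = 1e-9)
  expect_equal(cs$area3d_above, 3, tolerance = 1e-9)
  expect_length(cs$contours, 1L)

  h <- make_primitive("hemisphere", list(radius = 1, resolution = 96L))
  csh <- cross_section_at_plane(h, plane3d(c(0, 0, 1), 0))
  expect_equal(csh$area2d, pi, tolerance = 0.01 * pi)
  expect_equal(csh$area3d_above, 2 * pi, tolerance = 0.01 * 2 * pi)

  ratio_at <- function(n) {
    co <- make_primitive("cone", list(radius = 2, slope_deg = 30, resolution = n))
    cs <- cross_section_at_plane(co, plane3d(c(0, 0, 1), 0))
    cs$area3d_above / cs$area2d
  }
  target <- 1 / cos(30 * pi / 180)
  err_coarse <- abs(ratio_at(32L) - target)
  err_fine <- abs(ratio_at(128L) - target)
  expect_lt(err_fine, 2e-3)
  expect_lt(err_fine, err_coarse + 1e-12)
})

test_that("cross_section_at_plane degenerate cases and continuity", {
  cube <- unit_cube()
  expect_warning(cs <- cross_section_at_plane(cube, plane3d(c(0, 0, 1), 2)),
                 "entirely above")
  expect_equal(cs$area2d, 0)
  expect_equal(cs$area3d_above, 0)

  # both areas are continuous in the plane offset for a closed mesh
  offs <- c(0.3, 0.3001)
  a <- vapply(offs, function(o) {
    cs <- cross_section_at_plane(cube, plane3d(c(0, 0, 1), o))
    c(cs$area2d, cs$area3d_above)
  }, numeric(2))
  expect_lt(abs(a[1, 2] - a[1, 1]), 1e-3)
  expect_lt(abs(a[2, 2] - a[2, 1]), 1e-2)
})

test_that("alignment to the occlusal frame", {
  sm <- test_molar()
  # the cervix of the generated crown is the exact z = 0 collar at the rim;
  # a tight band selects only those coplanar vertices
  th <- seq(0, 2 * pi, length.out = 33L)[-33]
  poly <- cbind(4.9 * cos(th), 4.9 * sin(th), 0)
  band <- cervical_band(sm$mesh, poly, half_width = 1e-6)
  al <- align_to_occlusal_frame(sm$mesh, band, c(1, 0, 0))
  # already aligned: rotation is the identity (the transform may still
  # recentre the band centroid onto the origin), heights are untouched,
  # and re-aligning the result is the exact identity (idempotence)
  expect_equal(al$transform[1:3, 1:3], diag(3), tolerance = 1e-9)
  expect_lt(max(abs(al$mesh$vertices[, 3] - sm$mesh$vertices[, 3])), 1e-9)
  band_b <- cervical_band(al$mesh, cbind(poly[, 1:2], 0), half_width = 1e-6)
  al_b <- align_to_occlusal_frame(al$mesh, band_b, c(1, 0, 0))
  expect_equal(al_b$transform, diag(4), tolerance = 1e-9)
  expect_lt(max(abs(al_b$mesh$vertices - al$mesh$vertices)), 1e-9)

  # pre-rotate by a known rigid motion; alignment must undo it
  R <- rotation_matrix(c(0.2, 1, 0.4), 0.7)
  t <- c(3, -1, 2)
  rot <- rigid_transform_mesh(sm$mesh, R, t)
  poly_rot <- sweep(poly %*% t(R), 2L, t, "+")
  band_rot <- cervical_band(rot, poly_rot, half_width = 1e-6)
  al2 <- align_to_occlusal_frame(rot, band_rot, as.numeric(R %*% c(1, 0, 0)))
  expect_equal(al2$mesh$vertices, al$mesh$vertices, tolerance = 1e-6)

  # the standard 0.2 mm band selects a non-trivial set that stays within
  # the band of z = 0 after alignment
  band_wide <- cervical_band(rot, poly_rot, half_width = 0.2)
  al3 <- align_to_occlusal_frame(rot, band_wide, as.numeric(R %*% c(1, 0, 0)))
  expect_gt(length(band_wide$vertex_ids), length(band_rot$vertex_ids))
  expect_lt(max(abs(al3$mesh$vertices[band_wide$vertex_ids, 3])), 0.21)

  expect_error(align_to_occlusal_frame(rot, band_rot,
                                       al2$cervical_plane$normal),
               "parallel")
})

test_that("transforms serialize to row-major JSON and back", {
  tf <- diag(4); tf[1:3, 1:3] <- rotation_matrix(c(1, 1, 0), 0.5)
  tf[1:3, 4] <- c(1, 2, 3)
  f <- tempfile(fileext = ".json")
  write_transform_json(tf, f)
  expect_equal(read_transform_json(f), tf, tolerance = 1e-12)
})
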