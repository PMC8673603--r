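test_that("primitives hit their closed forms and converge under refinement", {
  disk <- make_primitive("flat_disk", list(radius = 5))
  expect_equal(surface_area(disk), pi * 25, tolerance = 0.005)

  cerv <- plane3d(c(0, 0, 1), 0)
  hemi <- make_primitive("hemisphere", list(radius = 1, resolution = 96L))
  expect_equal(occlusal_relief_index(hemi, cerv, fossa_point = c(0, 0, 0))$ori,
               2, tolerance = 0.01)

  target <- 1 / cos(pi / 6)
  err <- vapply(c(24L, 48L, 96L), function(n) {
    cone <- make_primitive("cone", list(radius = 2, slope_deg = 30,
                                        resolution = n))
    abs(occlusal_relief_index(cone, cerv, fossa_point = c(0, 0, 0))$ori - target)
  }, numeric(1))
  expect_lt(err[3], 0.01 * target)
  expect_lt(err[2], err[1])
  expect_lt(err[3], err[2])
  expect_error(make_primitive("torus"), "arg")
})

test_that("synthetic molar recovers constructed dips and compositions", {
  # one facet per phase, equal dips, areas in ratio 3:4:3 via the radii
  fac <- data.frame(label = c("1", "5", "9"),
                    center_x = c(2.0, -2.0, 0),
                    center_y = c(1.2, 1.2, -0.5),
                    azimuth_deg = c(90, 90, -90),
                    dip_deg = 20,
                    radius = 0.35 * sqrt(c(3, 4, 3)),
                    stringsAsFactors = FALSE)
  sm <- make_synthetic_molar(molar_spec(resolution = 100L, facets = fac))
  cerv <- plane3d(c(0, 0, 1), 0)
  ff <- sm$annotation$face_index[sm$annotation$facet_label == "1"]
  expect_equal(dip_angle(sm$mesh, ff, cerv), 20, tolerance = 0.5 / 20)
  comp <- wear_composition(phase_areas(sm$mesh, sm$annotation,
                                       default_facet_catalog()))
  expect_equal(as.numeric(comp), c(0.3, 0.4, 0.3), tolerance = 0.02 / 0.3)
})

test_that("molar ground truth tightens with resolution", {
  err_at <- function(res) {
    sm <- make_synthetic_molar(molar_spec(resolution = res))
    pa <- phase_areas(sm$mesh, sm$annotation, default_facet_catalog())
    m <- merge(pa$facets, sm$ground_truth, by = "label")
    max(abs(m$area_mm2.x / m$area_mm2.y - 1))
  }
  expect_lt(err_at(120L), 0.02)
  expect_lt(err_at(240L), 0.005)
})

test_that("generators are deterministic", {
  a <- make_synthetic_molar(molar_spec(resolution = 60L))
  b <- make_synthetic_molar(molar_spec(resolution = 60L))
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$mesh$faces, b$mesh$faces)
  expect_identical(a$annotation, b$annotation)

  c1 <- sample_cohort(cohort_spec(seed = 7L))
  c2 <- sample_cohort(cohort_spec(seed = 7L))
  expect_identical(c1, c2)
  c3 <- sample_cohort(cohort_spec(seed = 8L))
  expect_false(identical(c1$bpi_pct, c3$bpi_pct))
})

test_that("cohort sampler respects its specification", {
  g <- list(list(name = "g1", n = 400L, center = c(0.3, 0.4, 0.3),
                 ilr_cov = diag(0.2^2, 2L),
                 dip_mean = c(25, 25, 22), dip_sd = c(5, 5, 5),
                 ori_mean = 1.5, ori_sd = 0.1,
                 sex_freq = c(F = 0.5, M = 0.5),
                 age_freq = c(younger = 1)))
  tab <- sample_cohort(cohort_spec(groups = g, seed = 2L))
  ctr <- compositional_center(as.matrix(tab[, c("bpi_pct", "lpi_pct",
                                                "pii_pct")]) / 100)
  expect_lt(max(abs(ctr - c(0.3, 0.4, 0.3))), 0.02)

  # zero-noise limit: every composition equals the center
  g[[1]]$ilr_cov <- diag(1e-18, 2L)
  g[[1]]$n <- 10L
  tab0 <- sample_cohort(cohort_spec(groups = g, seed = 2L))
  expect_equal(tab0$bpi_pct, rep(30, 10L), tolerance = 1e-6)

  g[[1]]$ilr_cov <- matrix(c(1, 2, 2, 1), 2L)   # not positive definite
  expect_error(cohort_spec(groups = g), "positive definite")
})

test_that("antagonist pair styles differ as constructed", {
  pre <- make_antagonist_pair("preindustrial")
  ind <- make_antagonist_pair("industrial")
  expect_gt(nrow(pre$trajectory$waypoints), nrow(ind$trajectory$waypoints))
  expect_gt(pre$first_contact_distance, ind$first_contact_distance)
  # annotations label all three phase classes
  cls <- default_facet_catalog()[unique(pre$annotation$facet_label)]
  expect_setequal(as.character(cls), c("BPI", "LPI", "PII"))

  # degenerate trajectory that starts at intercuspation has no phase I steps
  w <- pre$trajectory$waypoints
  t0 <- trajectory(w[3:5, , drop = FALSE], intercuspation_index = 1L)
  lower_mi <- molarwear:::translate_mesh(pre$lower, -w[1, ])
  tl <- simulate_power_stroke(molarwear:::translate_mesh(lower_mi, w[3, ]),
                              pre$upper, pre$annotation,
                              default_facet_catalog(), t0,
                              simulation_config())
  expect_equal(sum(tl$phase == "I"), 0L)
  expect_gt(nrow(tl), 0L)
})

test_that("trajectory JSON round-trips with 0-based index on disk", {
  tr <- trajectory(rbind(c(0, 0, 0), c(0, 1, 0), c(0, 2, 0.2)), 2L)
  f <- tempfile(fileext = ".json")
  write_trajectory_json(tr, f)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(obj$intercuspation_index, 1L)
  back <- read_trajectory_json(f)
  expect_equal(back$waypoints, tr$waypoints)
  expect_equal(back$intercuspation_index, 2L)
  expect_error(trajectory(rbind(c(0, 0, 0), c(0, 0, 0)), 1L), "distinct")
  expect_error(trajectory(rbind(c(0, 0, 0), c(1, 0, 0)), 3L), "range")
})
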