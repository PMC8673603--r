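catalog <- default_facet_catalog()

test_that("facet catalog validates and round-trips", {
  expect_s3_class(catalog, "facet_catalog")
  expect_setequal(unique(unclass(catalog)), c("BPI", "LPI", "PII", "TIP_CRUSH"))
  expect_error(facet_catalog(c(a = "BPI", a = "LPI")), "duplicate")
  expect_error(facet_catalog(c(a = "PHASE9")), "unknown phase class")
  f <- tempfile(fileext = ".json")
  write_facet_catalog(catalog, f)
  expect_identical(unclass(read_facet_catalog(f)), unclass(catalog))
})

test_that("annotation CSV uses 0-based indices and validates labels", {
  ann <- facet_annotation(c(5L, 9L), c("1", "9"))
  f <- tempfile(fileext = ".csv")
  write_facet_annotation(ann, f)
  raw <- read.csv(f)
  expect_equal(raw$face_index, c(4L, 8L))
  expect_equal(read_facet_annotation(f)$face_index, c(5L, 9L))
  expect_error(facet_annotation(c(1L, 1L), c("1", "2")), "at most one")

  sm <- test_molar()
  bad <- facet_annotation(1L, "no_such_label")
  expect_error(phase_areas(sm$mesh, bad, catalog), "no_such_label")
})

test_that("phase areas recover construction and exclude tip crush", {
  sm <- test_molar()
  pa <- phase_areas(sm$mesh, sm$annotation, catalog)
  m <- merge(pa$facets, sm$ground_truth, by = "label")
  expect_lt(max(abs(m$area_mm2.x / m$area_mm2.y - 1)), 0.03)

  # removing the tip-crush labels never changes the phase totals
  keep <- sm$annotation$facet_label != "tc_protoconid"
  ann2 <- facet_annotation(sm$annotation$face_index[keep],
                           sm$annotation$facet_label[keep])
  pa2 <- phase_areas(sm$mesh, ann2, catalog)
  expect_equal(pa2$class_totals[c("BPI", "LPI", "PII")],
               pa$class_totals[c("BPI", "LPI", "PII")])
  expect_equal(pa2$class_totals[["TIP_CRUSH"]], 0)
  expect_equal(pa$wear_total,
               sum(pa$class_totals[c("BPI", "LPI", "PII")]))
})

test_that("wear_composition closes to one and flags boundaries", {
  expect_equal(as.numeric(wear_composition(c(3, 4, 3))), c(0.3, 0.4, 0.3))
  # the reported pre-industrial mean composition, on the percent scale
  # (the printed values total 99.99%, so closure divides by their sum)
  p <- wear_composition(c(30.88, 39.84, 29.27))
  expect_equal(as.numeric(p),
               c(30.88, 39.84, 29.27) / sum(c(30.88, 39.84, 29.27)),
               tolerance = 1e-12)
  expect_false(attr(p, "boundary"))
  b <- wear_composition(c(1, 0, 0))
  expect_equal(as.numeric(b), c(1, 0, 0))
  expect_true(attr(b, "boundary"))
  expect_error(wear_composition(c(0, 0, 0)), "zero")
})

test_that("dip angle: parallel, perpendicular, constructed", {
  cerv <- plane3d(c(0, 0, 1), 0)
  flat <- unit_plate(z0 = 5)
  expect_equal(dip_angle(flat, 1:2, cerv), 0, tolerance = 1e-9)

  vert <- triangle_mesh(rbind(c(0, 0, 0), c(0, 1, 0), c(0, 1, 1), c(0, 0, 1)),
                        rbind(c(1, 2, 3), c(1, 3, 4)), clean = FALSE)
  expect_equal(dip_angle(vert, 1:2, cerv), 90, tolerance = 1e-9)

  sm <- test_molar()
  for (i in seq_len(nrow(sm$ground_truth))) {
    lb <- sm$ground_truth$label[i]
    ff <- sm$annotation$face_index[sm$annotation$facet_label == lb]
    expect_equal(dip_angle(sm$mesh, ff, cerv), sm$ground_truth$dip_deg[i],
                 tolerance = 0.05 / sm$ground_truth$dip_deg[i])
  }
  expect_error(dip_angle(sm$mesh, integer(0), cerv), "no faces")
})

test_that("occlusal relief index on closed forms and the synthetic molar", {
  cerv <- plane3d(c(0, 0, 1), 0)
  disk <- make_primitive("flat_disk", list(radius = 2))
  expect_equal(occlusal_relief_index(disk, cerv, fossa_point = c(0, 0, 0))$ori,
               1, tolerance = 1e-9)
  hemi <- make_primitive("hemisphere", list(radius = 1, resolution = 96L))
  expect_equal(occlusal_relief_index(hemi, cerv, fossa_point = c(0, 0, 0))$ori,
               2, tolerance = 0.01)
  cone <- make_primitive("cone", list(radius = 2, slope_deg = 30,
                                      resolution = 96L))
  expect_equal(occlusal_relief_index(cone, cerv, fossa_point = c(0, 0, 0))$ori,
               1 / cos(pi / 6), tolerance = 0.01)

  sm <- test_molar()
  ori <- occlusal_relief_index(sm$mesh, cerv)
  expect_gt(ori$ori, 1)
  # auto-detected fossa sits in the central basin, not at the rim
  expect_lt(sqrt(sum(ori$fossa_point[1:2]^2)), 2)
  # explicit fossa point always wins
  ori2 <- occlusal_relief_index(sm$mesh, cerv, fossa_point = ori$fossa_point)
  expect_equal(ori2$ori, ori$ori)
})

test_that("composition, dips and ORI are scale invariant; areas scale by s^2", {
  sm <- test_molar()
  cerv <- plane3d(c(0, 0, 1), 0)
  s <- 2.5
  big <- triangle_mesh(sm$mesh$vertices * s, sm$mesh$faces, clean = FALSE)
  pa <- phase_areas(sm$mesh, sm$annotation, catalog)
  pb <- phase_areas(big, sm$annotation, catalog)
  expect_equal(pb$class_totals, s^2 * pa$class_totals, tolerance = 1e-9)
  expect_equal(wear_composition(pb), wear_composition(pa), tolerance = 1e-9)
  ff <- sm$annotation$face_index[sm$annotation$facet_label == "1"]
  expect_equal(dip_angle(big, ff, cerv), dip_angle(sm$mesh, ff, cerv),
               tolerance = 1e-9)
  o1 <- occlusal_relief_index(sm$mesh, cerv, fossa_point = c(0, 0, 0.5))$ori
  o2 <- occlusal_relief_index(big, cerv, fossa_point = c(0, 0, 0.5 * s))$ori
  expect_equal(o1, o2, tolerance = 1e-9)
  # and to rigid transforms
  R <- rotation_matrix(c(1, 0.3, 0.2), 0.9)
  rot <- rigid_transform_mesh(sm$mesh, R, c(1, 2, 3))
  cerv_rot <- plane3d(as.numeric(R %*% c(0, 0, 1)),
                      sum((R %*% c(0, 0, 0.5)) * (R %*% c(0, 0, 1))) +
                        sum((R %*% c(0, 0, 1)) * c(1, 2, 3)))
  o3 <- occlusal_relief_index(rot, cerv_rot,
                              fossa_point = as.numeric(R %*% c(0, 0, 0.5)) +
                                c(1, 2, 3))$ori
  expect_equal(o3, o1, tolerance = 1e-6)
})

test_that("metrics table: schema, duplicates, CSV round-trip, cohort sizes", {
  r1 <- tooth_record("a", "pre-industrial", "F", "younger",
                     c(0.3, 0.4, 0.3), c(25, 24, 20), 1.5)
  r2 <- tooth_record("b", "industrial", "M", "older",
                     c(0.25, 0.35, 0.4), c(30, 31, 26), 1.6)
  tab <- build_metrics_table(list(r1, r2))
  expect_equal(nrow(tab), 2L)
  expect_named(tab, c("specimen_id", "group", "sex", "age_class",
                      "bpi_pct", "lpi_pct", "pii_pct", "bpi_dip_deg",
                      "lpi_dip_deg", "pii_dip_deg", "ori"))
  expect_error(build_metrics_table(list(r1, r1)), "duplicate")

  f <- tempfile(fileext = ".csv")
  write_metrics_table(tab, f)
  back <- read_metrics_table(f)
  num <- vapply(tab, is.numeric, logical(1))
  expect_equal(as.matrix(back[, num]), as.matrix(tab[, num]), tolerance = 1e-6)

  cohort <- sample_cohort(cohort_spec(seed = 5L))
  expect_equal(nrow(cohort), 233L)
  expect_equal(as.vector(table(cohort$group)[c("pre-industrial", "industrial")]),
               c(130L, 103L))
  expect_error(tooth_record("x", "g", composition = c(0.5, 0.2, 0.2),
                            dips = c(1, 2, 3), ori = 1.4), "sum")
})
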