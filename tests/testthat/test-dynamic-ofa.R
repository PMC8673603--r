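catalog <- default_facet_catalog()

test_that("contact detection on parallel plates", {
  lower <- unit_plate(z0 = 0, n = 10L)
  # separated by 1 mm: no contact
  up_far <- unit_plate_down(z0 = 1, n = 10L)
  dc <- detect_contact(lower, up_far, eps = 0.02)
  expect_length(dc$faces, 0L)
  expect_equal(dc$area, 0)
  expect_equal(dc$penetration, 0)

  # 0.01 mm apart: essentially the whole plate is in contact
  up_near <- unit_plate_down(z0 = 0.01, n = 10L)
  dc2 <- detect_contact(lower, up_near, eps = 0.02)
  expect_gt(dc2$area, 0.9)
  expect_lte(dc2$area, 1 + 1e-9)
  expect_equal(dc2$penetration, 0)

  # overlapping by 0.1 mm: penetration equals the overlap
  up_pen <- unit_plate_down(z0 = -0.1, n = 10L)
  dc3 <- detect_contact(lower, up_pen, eps = 0.02)
  expect_equal(dc3$penetration, 0.1, tolerance = 1e-9)
})

test_that("advance_step: free motion, head-on wall, oblique deflection", {
  cfg <- simulation_config()
  lower <- unit_plate(z0 = 0, n = 4L)

  # free space: the full 0.05 mm step is taken
  far <- unit_plate_down(z0 = 5, n = 4L)
  st <- advance_step(lower, c(0, 0, 0), c(0, 0, 1), far, cfg)
  expect_equal(st$advanced, 0.05)
  expect_equal(st$status, "free")

  # head-on approach to a wall 0.03 mm away stops within tolerance
  wall <- unit_plate_down(z0 = 0.03, n = 4L)
  st2 <- advance_step(lower, c(0, 0, 0), c(0, 0, 1), wall, cfg)
  expect_lte(st2$contact$penetration, cfg$penetration_tol)
  expect_lte(st2$advanced, 0.03 + cfg$penetration_tol)
  expect_gt(st2$advanced, 0.01)

  # 45 degree approach: post-contact motion matches the projection oracle
  u <- c(0, 1, 1) / sqrt(2)
  st3 <- advance_step(lower, c(0, 0, 0.027), c(0, 1, 1.027), wall, cfg)
  moved <- st3$offset - c(0, 0, 0.027)
  n <- c(0, 0, 1)
  tang_oracle <- u - sum(u * n) * n           # pure tangential direction
  expect_gt(sum(moved * tang_oracle), 0)      # has a tangential component
  # no normal penetration growth: final z stays at the wall within tolerance
  expect_lte(st3$offset[3], 0.03 + cfg$penetration_tol)
  expect_equal(st3$status, "contact")

  # already-violated tolerance at zero advance reports a jam
  deep <- unit_plate_down(z0 = -0.05, n = 4L)
  st4 <- advance_step(lower, c(0, 0, 0), c(0, 0, 1), deep, cfg)
  expect_equal(st4$status, "jammed")
  expect_equal(st4$advanced, 0)
})

test_that("free-space trajectory yields >= 20 steps per mm, all zero contact", {
  lower <- unit_plate(z0 = 0, n = 4L)
  upper <- unit_plate_down(z0 = 5, n = 4L)
  ann <- facet_annotation(1L, "9")
  tr <- trajectory(rbind(c(0, 0, 0), c(1, 0, 0)), 2L)
  tl <- simulate_power_stroke(lower, upper, ann, catalog, tr,
                              simulation_config())
  expect_gte(nrow(tl), 20L)
  expect_true(all(tl$area_bpi + tl$area_lpi + tl$area_pii +
                    tl$area_unlabeled == 0))
  expect_true(all(tl$status == "free"))
})

test_that("power-stroke simulation is deterministic and physically bounded", {
  pair <- make_antagonist_pair("industrial")
  cfg <- simulation_config()
  tl1 <- simulate_power_stroke(pair$lower, pair$upper, pair$annotation,
                               catalog, pair$trajectory, cfg)
  tl2 <- simulate_power_stroke(pair$lower, pair$upper, pair$annotation,
                               catalog, pair$trajectory, cfg)
  expect_identical(as.data.frame(tl1), as.data.frame(tl2))

  ok <- tl1$status != "jammed"
  expect_true(all(tl1$penetration[ok] <= cfg$penetration_tol + 1e-12))
  total_area <- surface_area(pair$lower)
  expect_true(all(tl1$area_bpi + tl1$area_lpi + tl1$area_pii +
                    tl1$area_unlabeled <= total_area))

  # first contact within 2 timesteps of the constructed contact pose
  first <- which(tl1$area_bpi + tl1$area_lpi + tl1$area_pii +
                   tl1$area_unlabeled > 0)[1]
  n_phase1 <- sum(tl1$phase == "I")
  predicted <- n_phase1 - floor(pair$first_contact_distance / cfg$step_mm)
  expect_lte(abs(first - predicted), 2L)
})

test_that("cumulative contacted faces grow monotonically on pure approach", {
  lower <- unit_plate(z0 = 0, n = 8L)
  upper <- unit_plate_down(z0 = 0.2, n = 8L)
  seen <- integer(0)
  for (dz in seq(0, 0.19, by = 0.01)) {
    dc <- detect_contact(molarwear:::translate_mesh(lower, c(0, 0, dz)),
                         upper, eps = 0.02)
    expect_true(all(seen %in% union(seen, dc$faces)))
    seen_new <- union(seen, dc$faces)
    expect_gte(length(seen_new), length(seen))
    seen <- seen_new
  }
  expect_gt(length(seen), 0L)
})

test_that("halving the step changes the contact-area trace by < 5%", {
  pair <- make_antagonist_pair("industrial")
  run <- function(step) {
    cfg <- simulation_config(step_mm = step)
    tl <- simulate_power_stroke(pair$lower, pair$upper, pair$annotation,
                                catalog, pair$trajectory, cfg)
    # integrate labeled contact area over travelled distance
    sum((tl$area_bpi + tl$area_lpi + tl$area_pii) * step)
  }
  a1 <- run(0.05)
  a2 <- run(0.025)
  expect_lt(abs(a2 - a1) / a1, 0.05)
})

test_that("timeline summaries count phases and exclusive PII steps", {
  tl0 <- structure(data.frame(step = 1:3, phase = c("I", "I", "II"),
                              x = 0, y = 0, z = 0, area_bpi = 0, area_lpi = 0,
                              area_pii = 0, area_unlabeled = 0,
                              penetration = 0, status = "free"),
                   class = c("contact_timeline", "data.frame"))
  s0 <- timeline_summary(tl0)
  expect_equal(s0$contact_steps, 0L)
  expect_equal(s0$exclusive_pii_steps, 0L)

  tl1 <- tl0
  tl1$area_pii <- c(1, 1, 1)
  tl1$area_bpi <- c(0.5, 0, 0)
  s1 <- timeline_summary(rbind(tl1, tl1[3, ], tl1[3, ], tl1[3, ]))
  expect_equal(s1$exclusive_pii_steps, 5L)
  expect_equal(s1$phase1_steps, 2L)
})

test_that("simulation config validates its invariants", {
  expect_error(simulation_config(step_mm = 0.001, penetration_tol = 0.005),
               "step_mm")
  expect_error(simulation_config(contact_eps = -1), "contact_eps")
})
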