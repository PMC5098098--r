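# Limb geometry and electrode placement.

test_that("limb radii follow the thickness conventions", {
  m <- build_limb(muscle_thickness = 0.051, fat_thickness = 0.005)
  expect_equal(unname(m$layer_radii),
               c(0.007, 0.012, 0.0255, 0.0305))
  expect_true(all(diff(m$layer_radii) > 0))
  # outer-diameter convention: 50 mm value -> 25 mm outer radius
  m2 <- build_limb(0.050, 0.005, bone_radius = 0.010)
  expect_equal(m2$layer_radii[["muscle"]], 0.025)
  # per-side annular convention
  m3 <- build_limb(0.020, 0.005, thickness_convention = "annular")
  expect_equal(m3$layer_radii[["muscle"]],
               m3$layer_radii[["cortical_bone"]] + 0.020)
  # layer thicknesses partition the outer radius
  expect_equal(sum(diff(c(0, unname(m$layer_radii)))),
               m$layer_radii[["skin_fat"]])
  expect_error(build_limb(0.020, 0.005), "collapses")
})

test_that("muscle thickness updates preserve the other layers", {
  m <- build_limb()
  expect_equal(with_muscle_thickness(m, m$muscle_thickness), m)
  up <- with_muscle_thickness(m, 0.056)
  expect_gt(up$layer_radii[["skin_fat"]], m$layer_radii[["skin_fat"]])
  expect_equal(up$fat_thickness, m$fat_thickness)
  expect_equal(up$layer_radii[["cortical_bone"]],
               m$layer_radii[["cortical_bone"]])
  sweep <- lapply(c(41, 46, 51, 56) / 1000, with_muscle_thickness,
                  model = m)
  expect_equal(vapply(sweep, `[[`, 0, "fat_thickness"),
               rep(0.005, 4))
  expect_error(with_muscle_thickness(m, 0.01), "collapses")
})

test_that("electrode placement is ordered, disjoint and symmetric", {
  m <- build_limb()
  conv <- electrode_preset("conventional", m)
  p <- place_electrodes(m, conv)
  expect_equal(vapply(p, `[[`, "", "role"),
               c("drive_A", "sense_1", "sense_2", "drive_B"))
  z0 <- vapply(p, `[[`, 0, "z0"); z1 <- vapply(p, `[[`, 0, "z1")
  expect_true(all(z0[-1] > z1[-4]))                  # disjoint, ordered
  # reflection about mid-length maps A<->B and 1<->2
  expect_equal(m$length - rev(z1), z0, tolerance = 1e-12)
  # conventional electrodes: 65 mm arc x 7 mm axial at the default radius
  expect_equal(conv$drive_width, 0.007)
  arc <- 2 * conv$angular_halfwidth_drive * pi / 180 * 0.0305
  expect_equal(arc, 0.065, tolerance = 1e-9)
})

test_that("optimized preset reproduces the 87 mm drive separation", {
  opt <- electrode_preset("optimized")
  # 33 + 7 + 7 + 7 + 33 between drive inner edges
  expect_equal(drive_separation(opt) * 1000, 87)
  p <- place_electrodes(build_limb(), opt)
  expect_equal((p[[4]]$z0 - p[[1]]$z1) * 1000, 87, tolerance = 1e-9)
})

test_that("footprint overflow and full-ring limits are handled", {
  m <- build_limb()
  big <- electrode_config(0.04, 0.04, 90, 90, 0.05, 0.05)
  expect_error(place_electrodes(m, big), "exceeds")
  ring <- electrode_config(0.02, 0.002, 180, 180, 0.048, 0.1)
  p <- place_electrodes(homogeneous_limb(0.05, 0.5), ring)
  expect_equal(p[[1]]$theta_halfwidth, 180)
})
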