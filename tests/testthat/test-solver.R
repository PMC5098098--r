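# Forward-solver identities and derived quantities.

test_that("derived quantities follow the admittance algebra", {
  d <- derived_quantities(100 + 0i, 5e4)
  expect_equal(d$R_ohm, 100)
  expect_equal(d$X_ohm, 0)
  expect_equal(d$phase_deg, 0)
  expect_equal(d$G_S, 0.01)
  expect_equal(d$C_F, 0)

  # capacitive impedance with R = 30, X = 40 (reported positive)
  w <- 2 * pi * 1e4
  d <- derived_quantities(30 - 40i, 1e4)
  expect_equal(d$X_ohm, 40)
  expect_equal(d$G_S, 30 / 2500)
  expect_equal(d$C_F, 40 / (2500 * w))
  # round trip 1/Z = G + j*w*C
  Z_back <- 1 / complex(real = d$G_S, imaginary = w * d$C_F)
  expect_equal(Z_back, 30 - 40i, tolerance = 1e-14)

  # geometric factor output
  dk <- derived_quantities(30 - 40i, 1e4, K = 50)
  expect_equal(dk$sigma_S_per_m, 50 * dk$G_S)
  expect_error(derived_quantities(0 + 0i, 1e4), "nonzero")
})

test_that("reciprocity, linearity and conservation hold on a fixed mesh",
{
  mesh <- fx_mesh_coarse()
  lib <- fx_lib()
  s1 <- assemble_and_solve(mesh, lib, 5e4)
  s2 <- assemble_and_solve(mesh, lib, 5e4, swap_roles = TRUE)
  expect_lt(Mod(s1$Z - s2$Z) / Mod(s1$Z), 1e-8)
  s3 <- assemble_and_solve(mesh, lib, 5e4, drive_voltage = 2)
  expect_lt(Mod(s1$Z - s3$Z) / Mod(s1$Z), 1e-10)
  expect_equal(Mod(s3$I), 2 * Mod(s1$I), tolerance = 1e-10)
  expect_lt(s1$conservation, 1e-10)
  # current-driven mode: identical Z, prescribed current honoured
  s4 <- assemble_and_solve(mesh, lib, 5e4, drive_current = 1e-3)
  expect_identical(s4$Z, s1$Z)
  expect_equal(s4$I, 1e-3 + 0i, tolerance = 1e-14)
})

test_that("isotropic muscle is invariant to fiber-direction labelling", {
  lib <- make_tissue_library("normal", anisotropy_ratio = 1)
  swapped <- lib
  swapped$specs$muscle <- list(
    longitudinal = lib$specs$muscle$transverse,
    transverse = lib$specs$muscle$longitudinal)
  mesh <- fx_mesh_coarse()
  za <- assemble_and_solve(mesh, lib, 5e4)$Z
  zb <- assemble_and_solve(mesh, swapped, 5e4)$Z
  expect_identical(za, zb)
})

test_that("zero permittivity gives an exactly real impedance", {
  case <- oracle_case_layered()
  mesh <- generate_mesh(case$model, case$patches,
                        list(dr = 0.01, dtheta = 90, dz = 0.012))
  for (f in c(1e3, 5e4, 5e5)) {
    s <- assemble_and_solve(mesh, case$lib, f)
    expect_identical(Im(s$Z), 0)
  }
})

test_that("reactance spectrum peaks strictly inside the band and the
           atrophied spectrum separates at 50 kHz", {
  freqs <- 10^seq(3, log10(5e5), length.out = 9)
  sp <- spectrum(fx_model(), electrode_preset("conventional"), fx_lib(),
                 freqs, "coarse")
  imax <- which.max(sp$X_ohm)
  expect_gt(imax, 1)
  expect_lt(imax, length(freqs))
  expect_true(all(sp$X_ohm > 0))

  m46 <- with_muscle_thickness(fx_model(), 0.046)
  opt <- electrode_preset("optimized")
  xn <- spectrum(m46, opt, fx_lib(), 5e4, "coarse")$X_ohm
  xa <- spectrum(m46, opt, make_tissue_library("atrophied"), 5e4,
                 "coarse")$X_ohm
  expect_gt(abs(xn - xa) / xn, 0.05)
})

test_that("COCG agrees with the block-real direct solve", {
  mesh <- fx_mesh_coarse()
  lib <- fx_lib()
  zi <- assemble_and_solve(mesh, lib, 5e4, solver = "cocg")$Z
  zd <- assemble_and_solve(mesh, lib, 5e4, solver = "lu")$Z
  expect_lt(Mod(zi - zd) / Mod(zd), 1e-9)
})
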