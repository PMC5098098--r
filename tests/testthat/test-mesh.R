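# Conforming tensor-grid mesh generation.

test_that("mesh conforms to layer radii and resolves every patch", {
  mesh <- fx_mesh_coarse()
  model <- fx_model()
  for (rr in model$layer_radii)
    expect_true(any(abs(mesh$rn - rr) < 1e-12))
  # each patch covers >= 2 cells in both surface directions
  for (p in mesh$patches) {
    kset <- which(mesh$z >= p$z0 - 1e-9 & mesh$z <= p$z1 + 1e-9)
    expect_gte(length(kset), 3)
    hw <- p$theta_halfwidth * pi / 180
    jset <- which(pmin(mesh$theta, 2 * pi - mesh$theta) <= hw + 1e-7)
    expect_gte(length(jset), 3)
  }
  # all four electrode classes present on the surface
  expect_setequal(unique(mesh$cls[mesh$cls > 0]), 1:4)
  # coarse preset stays small
  expect_lte(mesh$N, 2e5)
})

test_that("halving all target spacings scales cells roughly eightfold", {
  model <- fx_model()
  patches <- place_electrodes(model, electrode_preset("conventional"))
  m1 <- generate_mesh(model, patches,
                      list(dr = 2.4e-3, dtheta = 24, dz = 8e-3))
  m2 <- generate_mesh(model, patches,
                      list(dr = 1.2e-3, dtheta = 12, dz = 4e-3))
  ratio <- m2$N / m1$N
  # snapped patch/layer breakpoints dilute the asymptotic factor of 8
  expect_gt(ratio, 5)
  expect_lt(ratio, 11)
})

test_that("sub-resolution electrodes are refused with a clear message", {
  model <- fx_model()
  tiny <- electrode_config(0.007, 0.00005, 60, 60, 0.030, 0.015)
  patches <- place_electrodes(model, tiny)
  expect_error(generate_mesh(model, patches, "coarse"),
               "minimum resolvable")
})

test_that("millimetre-scale point electrodes are meshed, not refused", {
  model <- fx_model()
  wide <- electrode_preset("wide", model)
  mesh <- generate_mesh(model, place_electrodes(model, wide), "coarse")
  expect_s3_class(mesh, "eim_mesh")
  expect_setequal(unique(mesh$cls[mesh$cls > 0]), 1:4)
})
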