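# Verification oracles: closed form, refinement study, gating.

test_that("ring-electrode closed form and its scalings", {
  expect_equal(ring_electrode_closed_form(1, 0.05, 0.03),
               0.03 / (pi * 0.0025))
  expect_equal(ring_electrode_closed_form(1, 0.05, 0.06),
               2 * ring_electrode_closed_form(1, 0.05, 0.03))
  expect_equal(ring_electrode_closed_form(1, 0.10, 0.03),
               ring_electrode_closed_form(1, 0.05, 0.03) / 4)
  expect_equal(round(ring_electrode_closed_form(1, 0.05, 0.03), 4),
               3.8197)
})

test_that("refinement study converges at second order with reciprocity
           at every level", {
  rep <- cached("conv_hom", brute_force_fine_grid(
    oracle_case_homogeneous(), nlev = 3))
  expect_gte(rep$order[length(rep$order)], 1.5)
  expect_lte(rep$order[length(rep$order)], 2.5)
  expect_true(rep$monotone)
  expect_true(all(rep$levels$reciprocity < 1e-8))
  # extrapolated reference within 1% of the closed form
  expect_lt(abs(Re(rep$Z_ref) - oracle_case_homogeneous()$R_ref) /
              oracle_case_homogeneous()$R_ref, 0.01)
})

test_that("layered case is self-consistent at mid resolution", {
  rep <- brute_force_fine_grid(oracle_case_layered(), nlev = 3)
  expect_lt(rep$levels$rel_error[2], 0.02)
  expect_true(all(rep$levels$reciprocity < 1e-8))
})

test_that("experiments refuse to run when the oracle gate fails", {
  os <- require_oracles("coarse")   # populates the cache, must pass
  expect_true(os$passed)
  # poison the cached suite and check the gate trips
  cache <- eimsim:::.oracle_cache
  good <- cache[["coarse"]]
  bad <- good
  bad$passed <- FALSE
  assign("coarse", bad, envir = cache)
  on.exit(assign("coarse", good, envir = cache), add = TRUE)
  expect_error(
    run_sweep(electrode_preset("conventional"), fx_lib(), "muscle",
              c(41, 51), 5e4, fx_model(), "coarse", gate = TRUE),
    "oracle suite failed")
})
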