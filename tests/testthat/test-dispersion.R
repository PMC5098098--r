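# Cole-Cole dispersion evaluation and the tissue library.

test_that("dispersion-free limit and hand-evaluated Debye point", {
  flat <- dispersion_spec(eps_inf = 50, sigma_static = 0.1)
  p <- evaluate_dispersion(flat, 5e4)
  expect_equal(p$sigma, 0.1)
  expect_equal(p$eps_r, 50)

  # single Debye term at omega*tau = 1: eps' = eps_inf + delta_eps/2
  debye <- dispersion_spec(4, 0.05, delta_eps = 1000, tau = 1e-6,
                           alpha = 0)
  f0 <- 1 / (2 * pi * 1e-6)
  p <- evaluate_dispersion(debye, f0)
  expect_equal(p$eps_r, 4 + 500, tolerance = 1e-12)

  expect_error(evaluate_dispersion(flat, -1), "positive")
})

test_that("sigma rises and eps_r falls with frequency for every default",
{
  lib <- fx_lib()
  grid <- 10^seq(3, log10(5e5), length.out = 40)
  specs <- c(lib$specs[c("marrow", "cortical_bone", "skin_fat")],
             lib$specs$muscle)
  for (sp in specs) {
    p <- evaluate_dispersion(sp, grid)
    expect_true(all(diff(p$sigma) >= -1e-12))
    expect_true(all(diff(p$eps_r) <= 1e-12))
    expect_true(all(is.finite(p$sigma)) && all(p$sigma > 0))
    expect_true(all(is.finite(p$eps_r)) && all(p$eps_r >= 1))
  }
})

test_that("library honours anisotropy ratio and atrophy localization", {
  lib <- make_tissue_library("normal", anisotropy_ratio = 3)
  f <- c(1e3, 5e4, 5e5)
  pr <- tissue_properties(lib, "muscle", f)
  expect_equal(pr$sigma$longitudinal, 3 * pr$sigma$transverse,
               tolerance = 1e-12)

  atr <- make_tissue_library("atrophied")
  for (nm in c("marrow", "cortical_bone", "skin_fat"))
    expect_identical(lib$specs[[nm]], atr$specs[[nm]])
  expect_false(identical(lib$specs$muscle, atr$specs$muscle))
  # default multipliers halve conductivity, scale permittivity by 0.6
  pa <- tissue_properties(atr, "muscle", 5e4)
  expect_equal(pa$sigma$transverse / pr$sigma$transverse[2], 0.5,
               tolerance = 0.2)

  expect_error(make_tissue_library("normal", anisotropy_ratio = 0.5),
               ">= 1")
})

test_that("perturbation is seeded, unit-mean and has the requested CV", {
  lib <- fx_lib()
  expect_identical(perturb_library(lib, 0, 1), lib)
  expect_identical(perturb_library(lib, 0.1, 7),
                   perturb_library(lib, 0.1, 7))
  expect_error(perturb_library(lib, 0.6, 1), "cv")

  mult <- vapply(1:100, function(s)
    perturb_library(lib, 0.1, s)$specs$skin_fat$sigma_static /
      lib$specs$skin_fat$sigma_static, 0)
  cv <- stats::sd(mult) / mean(mult)
  expect_gt(cv, 0.07)
  expect_lt(cv, 0.13)
})

test_that("shipped versioned defaults match the generated libraries", {
  for (cond in c("normal", "atrophied")) {
    path <- system.file("extdata",
                        paste0("tissue_library_", cond, "_v1.json"),
                        package = "eimsim")
    expect_true(nzchar(path))
    expect_equal(library_from_json(path), make_tissue_library(cond))
  }
})

test_that("JSON serialization round-trips the library", {
  lib <- make_tissue_library("atrophied", anisotropy_ratio = 2.5)
  path <- tempfile(fileext = ".json")
  library_to_json(lib, path)
  back <- library_from_json(path)
  expect_equal(back, lib)
  # solver-level properties agree too
  expect_equal(tissue_properties(back, "muscle", 5e4),
               tissue_properties(lib, "muscle", 5e4))
})
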