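# Sweeps, the step-change statistic and slope comparisons.

test_that("percent_change implements the step statistic", {
  expect_equal(percent_change(c(10, 8), c(40, 42)), -1.0)
  expect_equal(percent_change(rep(5, 4), c(1, 2, 3, 4)), rep(0, 3))
  t <- c(40, 45, 55)
  expect_equal(percent_change(2 * t, t), c(2, 2))
  expect_error(percent_change(1:3, c(1, 1, 2)), "repeated")
  expect_error(percent_change(1:3, 1:2), "equal length")
})

test_that("sweeps emit one record per value-frequency pair", {
  sw <- run_sweep(electrode_preset("conventional"), fx_lib(), "muscle",
                  c(46, 51), c(1e4, 5e4), fx_model(), "coarse",
                  gate = FALSE)
  expect_equal(nrow(sw), 4)
  expect_setequal(sw$value_mm, c(46, 51))
  expect_error(
    run_sweep(electrode_preset("conventional"), fx_lib(), "muscle",
              c(51, 46), 5e4, gate = FALSE), "increasing")
})

test_that("slope extraction matches OLS and flags exact linearity", {
  fake <- data.frame(frequency_Hz = 5e4, value_mm = c(40, 45, 50, 55),
                     X_ohm = 10 - 0.2 * c(40, 45, 50, 55),
                     R_ohm = 3 + 0.5 * c(40, 45, 50, 55),
                     variable = "muscle", config = "fake")
  class(fake) <- c("sweep_result", "data.frame")
  sx <- slope_from_sweep(fake, "X", 5e4)
  expect_equal(sx$slope, -0.2, tolerance = 1e-12)
  expect_equal(sx$r, -1, tolerance = 1e-12)
  sr <- slope_from_sweep(fake, "R", 5e4)
  expect_equal(sr$slope, 0.5, tolerance = 1e-12)
  expect_equal(sr$r, 1, tolerance = 1e-12)
  # degenerate constant response: zero slope, undefined correlation
  fake$X_ohm <- 7
  sd <- slope_from_sweep(fake, "X", 5e4)
  expect_equal(sd$slope, 0)
  expect_true(is.na(sd$r))
})

test_that("self-comparison is 0% and swapping configs is antisymmetric",
{
  sa <- fx_slope("conventional")
  sb <- fx_slope("optimized")
  self_red <- 100 * (abs(sa$slope) - abs(sa$slope)) / abs(sa$slope)
  expect_equal(self_red, 0)
  p <- 100 * (abs(sa$slope) - abs(sb$slope)) / abs(sa$slope)
  q <- 100 * (abs(sb$slope) - abs(sa$slope)) / abs(sb$slope)
  expect_equal(q, 100 * (1 - 1 / (1 - p / 100)), tolerance = 1e-10)
})

test_that("identical libraries give zero separation; separation grows
           with the atrophy multiplier", {
  lib <- fx_lib()
  rep0 <- disease_discrimination(electrode_preset("optimized"), lib, lib,
                                 fx_model(), 5e4, "coarse",
                                 gate = FALSE)
  expect_equal(rep0$table$abs_separation, 0)
  expect_false(rep0$distinguishable)

  seps <- vapply(c(0.8, 0.6, 0.4), function(fac) {
    atr <- make_tissue_library("atrophied", atrophy_sigma_factor = fac)
    disease_discrimination(electrode_preset("optimized"), lib, atr,
                           fx_model(), 5e4, "coarse",
                           gate = FALSE)$rel_separation_50k
  }, 0)
  expect_true(all(diff(seps) > 0))
})

test_that("sweep outputs are reproducible and stamped with the config
           hash", {
  cfg <- electrode_preset("optimized")
  s1 <- run_sweep(cfg, fx_lib(), "muscle", c(46, 51, 56), 5e4,
                  fx_model(), "coarse", gate = FALSE)
  s2 <- run_sweep(cfg, fx_lib(), "muscle", c(46, 51, 56), 5e4,
                  fx_model(), "coarse", gate = FALSE)
  expect_identical(s1, s2)
  expect_match(attr(s1, "config_hash"), "^[0-9a-f]{16}$")
  expect_identical(attr(s1, "config_hash"), config_hash(cfg))
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_result_csv(s1, p1); write_result_csv(s2, p2)
  expect_identical(readLines(p1), readLines(p2))
})
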