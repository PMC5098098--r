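# Thickness sweeps, the percentage-change statistic, regression-slope
# sensitivity (the GA fitness) and configuration comparisons.

#' Sweep an anatomical variable and record EIM parameters
#'
#' Rebuilds the limb for each thickness value (the other anatomical
#' variable held constant), solves at every frequency and tabulates the
#' derived quantities. Refuses to run unless the verification oracle suite
#' has passed at the requested resolution (see [require_oracles()]).
#'
#' @param config An `electrode_config`.
#' @param lib A `tissue_library`.
#' @param variable `"muscle"` or `"fat"`: which thickness is swept.
#' @param values_mm Strictly increasing thickness values in mm (>= 2).
#' @param frequencies Frequencies in Hz.
#' @param model Base `limb_model` providing the non-swept anatomy
#'   (default [build_limb()]).
#' @param resolution Mesh resolution.
#' @param gate Run the oracle gate first (default TRUE).
#' @return A `data.frame` of class `sweep_result`: one row per
#'   (value, frequency) with the derived quantities, the swept variable
#'   and the configuration label; the configuration hash is attached as an
#'   attribute.
#' @export
run_sweep <- function(config, lib, variable = c("muscle", "fat"),
                      values_mm, frequencies = 5e4,
                      model = build_limb(), resolution = "coarse",
                      gate = TRUE) {
  variable <- match.arg(variable)
  if (length(values_mm) < 2) stop("need at least 2 sweep values")
  if (is.unsorted(values_mm, strictly = TRUE))
    stop("sweep values must be strictly increasing")
  if (gate) require_oracles(resolution)
  rows <- list()
  for (v in values_mm) {
    m <- tryCatch(
      if (variable == "muscle") with_muscle_thickness(model, v / 1000)
      else with_fat_thickness(model, v / 1000),
      error = function(e) stop("sweep value ", v, " mm: ",
                               conditionMessage(e), call. = FALSE))
    patches <- place_electrodes(m, config)
    mesh <- generate_mesh(m, patches, resolution)
    for (f in frequencies) {
      s <- assemble_and_solve(mesh, lib, f)
      dq <- derived_quantities(s$Z, f)
      dq$Z_real <- Re(s$Z); dq$Z_imag <- Im(s$Z)
      dq$value_mm <- v
      rows[[length(rows) + 1L]] <- dq
    }
  }
  out <- do.call(rbind, rows)
  out$variable <- variable
  out$config <- config$label
  attr(out, "config_hash") <- config_hash(config)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Per-step normalized parameter change
#'
#' The step statistic `(new value - previous value) / change in thickness`
#' used to compare how strongly each EIM parameter responds to an
#' anatomical change (units: ohm/mm for R or X inputs).
#'
#' @param values Parameter values (length >= 2).
#' @param thicknesses Matching strictly increasing thicknesses, mm.
#' @return Numeric vector of length `length(values) - 1`.
#' @export
percent_change <- function(values, thicknesses) {
  if (length(values) != length(thicknesses) || length(values) < 2)
    stop("values and thicknesses must have equal length >= 2")
  dt <- diff(thicknesses)
  if (any(dt == 0)) stop("repeated thicknesses: step change undefined")
  diff(values) / dt
}

# OLS slope of y on x with correlation; degenerate (constant) responses
# yield slope 0 and r NA.
.ols <- function(x, y) {
  if (stats::sd(y) == 0)
    return(list(slope = 0, intercept = y[1], r = NA_real_))
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(x, y))
}

#' Regression-slope sensitivity of an EIM parameter to thickness
#'
#' Ordinary least-squares regression of the chosen parameter at one
#' frequency on the swept thickness. The magnitude of this slope is the
#' fitness minimized by the electrode-placement optimization (reactance at
#' 50 kHz versus muscle thickness).
#'
#' @inheritParams run_sweep
#' @param thicknesses_mm Strictly increasing thicknesses, mm (>= 3).
#' @param parameter `"X"` (reactance) or `"R"` (resistance).
#' @param frequency Single frequency, Hz (default 50 kHz).
#' @return A list of class `sensitivity_result`: `slope` (ohm/mm),
#'   `intercept` (ohm), `r`, `parameter`, `frequency`, `variable`,
#'   `config`, and the underlying `sweep`.
#' @export
sensitivity_slope <- function(config, lib, thicknesses_mm,
                              parameter = c("X", "R"), frequency = 5e4,
                              variable = c("muscle", "fat"),
                              model = build_limb(),
                              resolution = "coarse", gate = TRUE) {
  parameter <- match.arg(parameter)
  variable <- match.arg(variable)
  if (length(thicknesses_mm) < 3) stop("need at least 3 thicknesses")
  sw <- run_sweep(config, lib, variable, thicknesses_mm, frequency,
                  model, resolution, gate)
  slope_from_sweep(sw, parameter, frequency)
}

#' Compute a sensitivity slope from an existing sweep table
#'
#' @param sweep A `sweep_result`.
#' @param parameter `"X"` or `"R"`.
#' @param frequency Frequency (must be present in the sweep).
#' @return A `sensitivity_result` (see [sensitivity_slope()]).
#' @export
slope_from_sweep <- function(sweep, parameter = c("X", "R"),
                             frequency = 5e4) {
  parameter <- match.arg(parameter)
  rows <- sweep[abs(sweep$frequency_Hz - frequency) < 1e-6, ]
  if (nrow(rows) < 3) stop("sweep lacks rows at frequency ", frequency)
  y <- if (parameter == "X") rows$X_ohm else rows$R_ohm
  fit <- .ols(rows$value_mm, y)
  structure(list(slope = fit$slope, intercept = fit$intercept, r = fit$r,
                 parameter = parameter, frequency = frequency,
                 variable = rows$variable[1], config = rows$config[1],
                 sweep = sweep),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf(
    "<sensitivity_result> %s @ %g kHz vs %s thickness [%s]\n",
    x$parameter, x$frequency / 1e3, x$variable, x$config))
  cat(sprintf("  slope %.4g ohm/mm, intercept %.4g ohm, r %.4f\n",
              x$slope, x$intercept, x$r))
  invisible(x)
}

#' Percent reduction in slope magnitude between two configurations
#'
#' `100 * (|slope_a| - |slope_b|) / |slope_a|`, with `a` the baseline
#' (conventional) configuration: positive when `b` is less sensitive.
#'
#' @param config_a Baseline `electrode_config`.
#' @param config_b Candidate `electrode_config`.
#' @inheritParams sensitivity_slope
#' @return A list of class `config_comparison`: `reduction_percent`,
#'   `slope_a`, `slope_b` (full `sensitivity_result`s).
#' @export
compare_configs <- function(config_a, config_b, lib,
                            variable = c("muscle", "fat"),
                            thicknesses_mm, parameter = c("X", "R"),
                            frequency = 5e4, model = build_limb(),
                            resolution = "coarse", gate = TRUE) {
  variable <- match.arg(variable)
  parameter <- match.arg(parameter)
  sa <- sensitivity_slope(config_a, lib, thicknesses_mm, parameter,
                          frequency, variable, model, resolution, gate)
  sb <- sensitivity_slope(config_b, lib, thicknesses_mm, parameter,
                          frequency, variable, model, resolution,
                          gate = FALSE)
  if (abs(sa$slope) == 0)
    stop("baseline slope is zero: reduction undefined")
  structure(list(
    reduction_percent = 100 * (abs(sa$slope) - abs(sb$slope)) /
      abs(sa$slope),
    slope_a = sa, slope_b = sb), class = "config_comparison")
}

#' Normal-versus-atrophied discrimination under a configuration
#'
#' Solves both conditions over a frequency grid and reports the reactance
#' separation; the configuration is flagged as discriminating when the
#' relative separation at 50 kHz exceeds `threshold`.
#'
#' @param config An `electrode_config`.
#' @param lib_normal,lib_atrophied Tissue libraries sharing all non-muscle
#'   entries.
#' @param model A `limb_model`.
#' @param frequencies Frequency grid, Hz (should include 50 kHz).
#' @param resolution Mesh resolution.
#' @param threshold Relative separation flag level (default 0.05).
#' @param gate Run the oracle gate first.
#' @return List of class `discrimination_report`: per-frequency table
#'   (`frequency_Hz`, `X_normal`, `X_atrophied`, `abs_separation`,
#'   `rel_separation`), `rel_separation_50k`, `distinguishable`.
#' @export
disease_discrimination <- function(config, lib_normal, lib_atrophied,
                                   model = build_limb(),
                                   frequencies = c(1e4, 2e4, 5e4, 1e5,
                                                   2e5),
                                   resolution = "coarse",
                                   threshold = 0.05, gate = TRUE) {
  for (nm in setdiff(names(lib_normal$specs), "muscle")) {
    if (!identical(lib_normal$specs[[nm]], lib_atrophied$specs[[nm]]))
      stop("libraries differ outside the muscle entries ('", nm, "')")
  }
  if (gate) require_oracles(resolution)
  sp_n <- spectrum(model, config, lib_normal, frequencies, resolution)
  sp_a <- spectrum(model, config, lib_atrophied, frequencies, resolution)
  tab <- data.frame(frequency_Hz = frequencies,
                    X_normal = sp_n$X_ohm, X_atrophied = sp_a$X_ohm,
                    R_normal = sp_n$R_ohm, R_atrophied = sp_a$R_ohm)
  tab$abs_separation <- abs(tab$X_normal - tab$X_atrophied)
  tab$rel_separation <- tab$abs_separation / abs(tab$X_normal)
  i50 <- which.min(abs(frequencies - 5e4))
  structure(list(table = tab,
                 rel_separation_50k = tab$rel_separation[i50],
                 threshold = threshold,
                 distinguishable = tab$rel_separation[i50] > threshold),
            class = "discrimination_report")
}
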