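# Named experiments tying the modules together. Each experiment writes
# plain-text artifacts (CSV tables, JSON summaries) plus a run manifest
# into an output directory; the analysis/ driver scripts are thin wrappers
# around these.

.write_json <- function(x, path) {
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null"), path)
  invisible(path)
}

.manifest <- function(out_dir, name, cfg_hash, seed, resolution, files) {
  man <- list(experiment = name, config_hash = cfg_hash, seed = seed,
              mesh_resolution = if (is.list(resolution)) "explicit"
                                else resolution,
              tool_version = as.character(
                utils::packageVersion("eimsim")),
              timestamp = format(Sys.time(), tz = "UTC",
                                 "%Y-%m-%dT%H:%M:%SZ"),
              outputs = files)
  .write_json(man, file.path(out_dir, paste0(name, "_manifest.json")))
  man
}

#' Run a named experiment
#'
#' The experiment set mirrors the in-silico study: thickness sweeps of the
#' EIM parameters, configuration slope comparisons, disease
#' discrimination, the wide-configuration regression line, point-versus-
#' rectangular electrodes, the GA optimization, and the verification
#' oracle suite. All sensitivity and GA experiments are gated by
#' [require_oracles()].
#'
#' @param name One of `"fig2_sweeps"`, `"fig4_compare"`, `"fig5_disease"`,
#'   `"fig6_wide_slope"`, `"fig7_point_vs_rect"`, `"ga_optimize"`,
#'   `"oracle_suite"` (names follow the figures of the modelled study
#'   layout: sweeps, comparisons, discrimination, wide-config slope,
#'   point-electrode comparison, optimization history).
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed for stochastic experiments.
#' @param resolution Mesh resolution for the forward solves.
#' @param lib Tissue library (default: normal condition).
#' @param model Base limb model.
#' @param ga_seeds Seeds for the GA experiment.
#' @param ga Template [ga_config()] for the GA experiment.
#' @return The run manifest, invisibly; artifacts are written to
#'   `out_dir`.
#' @export
run_experiment <- function(name = c("fig2_sweeps", "fig4_compare",
                                    "fig5_disease", "fig6_wide_slope",
                                    "fig7_point_vs_rect", "ga_optimize",
                                    "oracle_suite"),
                           out_dir = "results", seed = 1,
                           resolution = "coarse",
                           lib = make_tissue_library(),
                           model = build_limb(),
                           ga_seeds = seed + 1:3,
                           ga = ga_config(population_size = 20,
                                          max_generations = 30,
                                          stall_generations = 15)) {
  name <- match.arg(name)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  # log-spaced band including the 50 kHz working frequency exactly
  freqs <- sort(unique(c(5e4, 10^seq(log10(1e3), log10(5e5),
                                     length.out = 12))))
  files <- character(0)
  emit <- function(df, fname) {
    path <- file.path(out_dir, fname)
    write_result_csv(df, path)
    files <<- c(files, path)
  }
  cfg_hash <- NA_character_

  if (name == "oracle_suite") {
    os <- oracle_suite(resolution)
    rep <- brute_force_fine_grid(oracle_case_homogeneous())
    out <- list(suite = list(
                  resolution = os$resolution, passed = os$passed,
                  closed_form = os$closed_form,
                  reciprocity = os$reciprocity,
                  conservation = os$conservation),
                convergence = list(order = rep$order,
                                   Z_ref_real = Re(rep$Z_ref),
                                   monotone = rep$monotone,
                                   levels = rep$levels))
    path <- file.path(out_dir, "oracle_suite.json")
    .write_json(out, path)
    files <- c(files, path)
    cfg_hash <- config_hash(list(name, resolution))
    if (!os$passed) stop("oracle suite FAILED; see ", path)
  } else if (name == "fig2_sweeps") {
    conv <- electrode_preset("conventional", model)
    cfg_hash <- config_hash(conv)
    swm <- run_sweep(conv, lib, "muscle", c(41, 46, 51, 56), freqs,
                     model, resolution)
    swf <- run_sweep(conv, lib, "fat", c(3, 5, 7, 9), freqs, model,
                     resolution)
    emit(swm, "fig2_muscle_sweep.csv")
    emit(swf, "fig2_fat_sweep.csv")
  } else if (name == "fig4_compare") {
    conv <- electrode_preset("conventional", model)
    opt <- electrode_preset("optimized", model)
    cfg_hash <- config_hash(list(conv, opt))
    cmp_x <- compare_configs(conv, opt, lib, "muscle", c(41, 46, 51, 56),
                             "X", 5e4, model, resolution)
    cmp_r <- compare_configs(conv, opt, lib, "fat", c(3, 5, 7, 9),
                             "R", 5e4, model, resolution)
    emit(cmp_x$slope_a$sweep, "fig4a_conventional_muscle.csv")
    emit(cmp_x$slope_b$sweep, "fig4a_optimized_muscle.csv")
    emit(cmp_r$slope_a$sweep, "fig4b_conventional_fat.csv")
    emit(cmp_r$slope_b$sweep, "fig4b_optimized_fat.csv")
    path <- file.path(out_dir, "fig4_reductions.json")
    .write_json(list(
      reactance_muscle_reduction_percent = cmp_x$reduction_percent,
      resistance_fat_reduction_percent = cmp_r$reduction_percent,
      slope_conventional_X_muscle = cmp_x$slope_a$slope,
      slope_optimized_X_muscle = cmp_x$slope_b$slope,
      slope_conventional_R_fat = cmp_r$slope_a$slope,
      slope_optimized_R_fat = cmp_r$slope_b$slope), path)
    files <- c(files, path)
  } else if (name == "fig5_disease") {
    opt <- electrode_preset("optimized", model)
    cfg_hash <- config_hash(opt)
    m46 <- with_muscle_thickness(model, 0.046)
    rep <- disease_discrimination(opt, lib,
                                  make_tissue_library("atrophied"),
                                  m46, freqs, resolution)
    emit(rep$table, "fig5_discrimination.csv")
    path <- file.path(out_dir, "fig5_summary.json")
    .write_json(list(rel_separation_50k = rep$rel_separation_50k,
                     threshold = rep$threshold,
                     distinguishable = rep$distinguishable), path)
    files <- c(files, path)
  } else if (name == "fig6_wide_slope") {
    wide <- electrode_preset("wide", model)
    opt <- electrode_preset("optimized", model)
    cfg_hash <- config_hash(list(wide, opt))
    sw <- sensitivity_slope(wide, lib, c(41, 46, 51, 56), "X", 5e4,
                            "muscle", model, resolution)
    so <- sensitivity_slope(opt, lib, c(41, 46, 51, 56), "X", 5e4,
                            "muscle", model, resolution, gate = FALSE)
    emit(sw$sweep, "fig6_wide_muscle_sweep.csv")
    path <- file.path(out_dir, "fig6_slopes.json")
    .write_json(list(slope_wide = sw$slope, slope_optimized = so$slope,
                     r_wide = sw$r, r_optimized = so$r), path)
    files <- c(files, path)
  } else if (name == "fig7_point_vs_rect") {
    rect <- electrode_preset("conventional", model)
    pt <- electrode_preset("point", model)
    cfg_hash <- config_hash(list(rect, pt))
    sr <- sensitivity_slope(rect, lib, c(41, 46, 51, 56), "X", 5e4,
                            "muscle", model, resolution)
    sp <- sensitivity_slope(pt, lib, c(41, 46, 51, 56), "X", 5e4,
                            "muscle", model, resolution, gate = FALSE)
    emit(sr$sweep, "fig7_rectangular_sweep.csv")
    emit(sp$sweep, "fig7_point_sweep.csv")
    path <- file.path(out_dir, "fig7_slopes.json")
    .write_json(list(slope_rectangular = sr$slope, slope_point = sp$slope,
                     point_less_sensitive =
                       abs(sp$slope) < abs(sr$slope)), path)
    files <- c(files, path)
  } else if (name == "ga_optimize") {
    cfg_hash <- config_hash(ga)
    res <- optimize_electrodes(ga_seeds, lib = lib, ga = ga,
                               model = model)
    hist <- do.call(rbind, lapply(seq_along(res$runs), function(i) {
      h <- res$runs[[i]]$history
      h$seed <- res$seeds[i]
      h
    }))
    emit(hist, "ga_history.csv")
    path <- file.path(out_dir, "ga_best.json")
    .write_json(list(seeds = res$seeds,
                     best_individuals =
                       apply(res$best_individuals, 1, as.list),
                     consensus = as.list(res$consensus),
                     drive_separation_mm = res$drive_separation_mm),
                path)
    files <- c(files, path)
  }
  invisible(.manifest(out_dir, name, cfg_hash, seed, resolution, files))
}
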