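# Bound-constrained genetic algorithm over the four electrode-placement
# variables: x1 = drive angular halfwidth (deg), x2 = sense angular
# halfwidth (deg), x3 = sense-sense gap (mm), x4 = sense-drive gap (mm).
# Operators follow the classical named set: stochastic uniform
# selection over rank-scaled expectations, arithmetic (convex) crossover,
# adaptive feasible (bounds-respecting, step-adapting) mutation, elitism.

#' Genetic-algorithm configuration
#'
#' @param population_size Number of individuals (default 100).
#' @param elite_count Individuals copied unchanged each generation
#'   (default 2); guarantees non-increasing best fitness.
#' @param crossover_fraction Fraction of the non-elite offspring produced
#'   by crossover (default 0.8); the remainder are mutants.
#' @param bounds 4x2 matrix of lower/upper bounds. Defaults: angles
#'   3-90 degrees per side, gaps 3-33 mm.
#' @param max_generations Generation cap (default 100).
#' @param stall_generations Stop after this many generations without best
#'   fitness improving by more than `fitness_tol` (default 50).
#' @param fitness_tol Improvement tolerance for the stall test.
#' @param initial_step Initial mutation step as a fraction of the bound
#'   range (default 0.2).
#' @param seed Integer seed; a run is fully reproducible given the seed.
#' @return List of class `ga_config`.
#' @export
ga_config <- function(population_size = 100, elite_count = 2,
                      crossover_fraction = 0.8,
                      bounds = default_ga_bounds(),
                      max_generations = 100, stall_generations = 50,
                      fitness_tol = 1e-6, initial_step = 0.2,
                      seed = 1) {
  bounds <- as.matrix(bounds)
  stopifnot(ncol(bounds) == 2, all(bounds[, 1] < bounds[, 2]),
            crossover_fraction >= 0, crossover_fraction <= 1,
            elite_count >= 0, elite_count < population_size,
            population_size >= 2, max_generations >= 1)
  structure(list(population_size = as.integer(population_size),
                 elite_count = as.integer(elite_count),
                 crossover_fraction = crossover_fraction,
                 bounds = bounds,
                 max_generations = as.integer(max_generations),
                 stall_generations = as.integer(stall_generations),
                 fitness_tol = fitness_tol,
                 initial_step = initial_step,
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Default electrode-variable bounds
#'
#' Angular coverage 3-90 degrees per side of the symmetry plane for drive
#' and sense electrodes; interelectrode gaps 3-33 mm.
#'
#' @return A 4x2 matrix with rownames
#'   `drive_halfwidth_deg`, `sense_halfwidth_deg`, `gap_sense_sense_mm`,
#'   `gap_sense_drive_mm`.
#' @export
default_ga_bounds <- function() {
  b <- rbind(drive_halfwidth_deg = c(3, 90),
             sense_halfwidth_deg = c(3, 90),
             gap_sense_sense_mm = c(3, 33),
             gap_sense_drive_mm = c(3, 33))
  colnames(b) <- c("lower", "upper")
  b
}

#' Stochastic uniform selection (SUS)
#'
#' Lays the rank-scaled expectations on a line and walks it with
#' equally-spaced pointers from a single uniform random offset, so every
#' individual is selected within one of its scaled expectation
#' (low-variance fitness-proportional selection). Fitness is minimized;
#' expectations are rank-scaled as 1/sqrt(rank).
#'
#' @param fitnesses Numeric fitness values (lower is better).
#' @param n_parents Number of parents to draw.
#' @return Integer vector of selected indices (length `n_parents`).
#' @export
stochastic_uniform_select <- function(fitnesses, n_parents) {
  stopifnot(n_parents >= 1)
  n <- length(fitnesses)
  rk <- rank(fitnesses, ties.method = "average")
  scaled <- 1 / sqrt(rk)
  expect <- n_parents * scaled / sum(scaled)
  cum <- cumsum(expect)
  offset <- stats::runif(1)
  pointers <- offset + seq_len(n_parents) - 1
  idx <- findInterval(pointers, cum) + 1L
  idx[idx > n] <- n  # guard against floating-point edge at the line end
  idx
}

#' Arithmetic (convex-combination) crossover
#'
#' `child = lambda * p1 + (1 - lambda) * p2` with a single
#' `lambda ~ U(0, 1)` per mating; the child is feasible by convexity of
#' the bound box.
#'
#' @param p1,p2 Parent vectors (within bounds).
#' @param lambda Optional fixed weight (default: drawn uniformly).
#' @return Child vector.
#' @export
arithmetic_crossover <- function(p1, p2, lambda = NULL) {
  if (is.null(lambda)) lambda <- stats::runif(1)
  lambda * p1 + (1 - lambda) * p2
}

#' Adaptive feasible mutation
#'
#' Adds a random direction scaled by `step * (upper - lower)` per
#' component and clips to the bounds, so mutants are always feasible. The
#' caller adapts `step`: it expands (x1.5) after a generation that
#' improved the best fitness and contracts (x0.5) otherwise, within
#' [0.02, 1] (the floor keeps exploration alive on flat landscapes).
#'
#' @param ind Individual (within bounds).
#' @param bounds Bounds matrix.
#' @param step Step fraction of the bound range (>= 0).
#' @return Mutant vector (within bounds).
#' @export
adaptive_feasible_mutation <- function(ind, bounds, step) {
  stopifnot(step >= 0)
  if (step == 0) return(ind)
  d <- stats::runif(length(ind), -1, 1)
  mut <- ind + step * (bounds[, 2] - bounds[, 1]) * d
  pmin(pmax(mut, bounds[, 1]), bounds[, 2])
}

# offspring accounting: elites + crossover children + mutants = N
.offspring_counts <- function(cfg) {
  n_cross <- round(cfg$crossover_fraction *
                     (cfg$population_size - cfg$elite_count))
  list(elite = cfg$elite_count, cross = n_cross,
       mutant = cfg$population_size - cfg$elite_count - n_cross)
}

#' Run the genetic algorithm
#'
#' Seeded, reproducible minimization of `fitness` over the bound box.
#' Individuals evaluating to non-finite fitness are assigned the worst
#' rank (with a warning) rather than aborting the run.
#'
#' @param fitness Function mapping a length-4 individual to a scalar
#'   fitness (minimized).
#' @param cfg A [ga_config()].
#' @param verbose Print per-generation progress.
#' @return List of class `ga_result`: `best` (individual), `best_fitness`,
#'   `history` (per generation: best/mean fitness, best individual,
#'   mutation step), `generations`, `mutation_step` (final).
#' @export
run_ga <- function(fitness, cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "ga_config"))
  has_seed <- exists(".Random.seed", envir = globalenv(),
                     inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)
  nb <- nrow(cfg$bounds)
  N <- cfg$population_size
  lower <- cfg$bounds[, 1]; upper <- cfg$bounds[, 2]
  pop <- t(replicate(N, lower + stats::runif(nb) * (upper - lower)))
  evaluate <- function(p) {
    f <- apply(p, 1, fitness)
    bad <- !is.finite(f)
    if (any(bad)) {
      warning(sum(bad), " individual(s) returned non-finite fitness; ",
              "ranked worst")
      worst <- if (all(bad)) 1 else max(f[!bad], 0)
      f[bad] <- 2 * worst + 1
    }
    f
  }
  fit <- evaluate(pop)
  counts <- .offspring_counts(cfg)
  step <- cfg$initial_step
  hist_best <- hist_mean <- hist_step <- numeric(0)
  hist_ind <- NULL
  best_prev <- Inf
  stall <- 0L
  gen <- 0L
  repeat {
    gen <- gen + 1L
    ord <- order(fit)
    best <- fit[ord[1]]
    hist_best <- c(hist_best, best)
    hist_mean <- c(hist_mean, mean(fit))
    hist_step <- c(hist_step, step)
    hist_ind <- rbind(hist_ind, pop[ord[1], ])
    if (verbose)
      cat(sprintf("gen %3d best %.6g mean %.6g step %.3f\n", gen, best,
                  mean(fit), step))
    improved <- best < best_prev - cfg$fitness_tol
    stall <- if (improved) 0L else stall + 1L
    best_prev <- min(best_prev, best)
    if (gen >= cfg$max_generations || stall >= cfg$stall_generations)
      break
    # step adaptation: expand on success, contract on failure
    step <- if (improved) min(1, step * 1.5) else max(0.02, step * 0.5)

    elites <- pop[ord[seq_len(counts$elite)], , drop = FALSE]
    n_parents <- 2L * counts$cross + counts$mutant
    parents <- stochastic_uniform_select(fit, n_parents)
    parents <- parents[sample.int(n_parents)]  # decorrelate pairings
    children <- matrix(NA_real_, counts$cross, nb)
    for (i in seq_len(counts$cross)) {
      children[i, ] <- arithmetic_crossover(pop[parents[2 * i - 1], ],
                                            pop[parents[2 * i], ])
    }
    mut_src <- parents[2L * counts$cross + seq_len(counts$mutant)]
    mutants <- matrix(NA_real_, counts$mutant, nb)
    for (i in seq_len(counts$mutant)) {
      mutants[i, ] <- adaptive_feasible_mutation(pop[mut_src[i], ],
                                                 cfg$bounds, step)
    }
    new_pop <- rbind(elites, children, mutants)
    new_fit <- c(fit[ord[seq_len(counts$elite)]],
                 evaluate(new_pop[-seq_len(counts$elite), , drop = FALSE]))
    pop <- new_pop
    fit <- new_fit
  }
  ord <- order(fit)
  vars <- rownames(cfg$bounds)
  best_ind <- stats::setNames(pop[ord[1], ], vars)
  colnames(hist_ind) <- vars
  structure(list(best = best_ind, best_fitness = fit[ord[1]],
                 history = data.frame(generation = seq_len(gen),
                                      best_fitness = hist_best,
                                      mean_fitness = hist_mean,
                                      mutation_step = hist_step,
                                      hist_ind),
                 generations = gen, mutation_step = step,
                 config = cfg),
            class = "ga_result")
}

#' Electrode configuration corresponding to a GA individual
#'
#' Fixed 7 mm axial electrode widths; the individual supplies the angular
#' halfwidths and the two gaps (mm).
#'
#' @param ind Length-4 individual
#'   (drive halfwidth deg, sense halfwidth deg, gap_ss mm, gap_sd mm).
#' @param electrode_width Axial width of all four electrodes, m.
#' @return An `electrode_config`.
#' @export
individual_to_config <- function(ind, electrode_width = 0.007) {
  electrode_config(drive_width = electrode_width,
                   sense_width = electrode_width,
                   angular_halfwidth_drive = ind[[1]],
                   angular_halfwidth_sense = ind[[2]],
                   gap_sense_sense = ind[[3]] / 1000,
                   gap_sense_drive = ind[[4]] / 1000,
                   label = "ga_individual")
}

#' Sensitivity-slope GA fitness factory
#'
#' Returns the fitness used for electrode optimization: the magnitude of
#' the OLS slope of reactance at 50 kHz versus muscle thickness for the
#' configuration encoded by an individual.
#'
#' @param lib Tissue library.
#' @param thicknesses_mm Muscle thickness grid, mm (>= 3 values).
#' @param model Base limb model.
#' @param resolution Mesh resolution used inside the fitness (default
#'   coarse, for speed).
#' @param parameter,frequency Regressed parameter and frequency.
#' @param electrode_width Axial electrode width, m.
#' @return Function: individual -> |slope| (ohm/mm); returns `Inf` for
#'   individuals whose footprint does not fit the model.
#' @export
slope_fitness <- function(lib, thicknesses_mm = c(41, 48.5, 56),
                          model = build_limb(), resolution = "coarse",
                          parameter = "X", frequency = 5e4,
                          electrode_width = 0.007) {
  require_oracles(resolution)
  function(ind) {
    cfg <- individual_to_config(ind, electrode_width)
    val <- tryCatch(
      abs(sensitivity_slope(cfg, lib, thicknesses_mm, parameter,
                            frequency, "muscle", model, resolution,
                            gate = FALSE)$slope),
      error = function(e) Inf)
    val
  }
}

#' Run the electrode-placement optimization over several seeds
#'
#' Repeats [run_ga()] with the slope fitness for each seed and summarizes
#' the per-seed best individuals and their component-wise median (the
#' consensus individual).
#'
#' @param seeds Integer vector of seeds.
#' @param lib Tissue library.
#' @param ga Template [ga_config()] (its `seed` field is overridden).
#' @param ... Passed to [slope_fitness()].
#' @return List of class `ga_consensus`: `runs` (list of `ga_result`),
#'   `best_individuals` (matrix, one row per seed), `consensus`
#'   (component medians), `drive_separation_mm` (inner-edge drive
#'   separation of the consensus individual, mm, for 7 mm sense widths).
#' @export
optimize_electrodes <- function(seeds, lib = make_tissue_library(),
                                ga = ga_config(), ...) {
  fit <- slope_fitness(lib, ...)
  runs <- lapply(seeds, function(s) {
    cfg <- ga
    cfg$seed <- as.integer(s)
    run_ga(fit, cfg)
  })
  bests <- do.call(rbind, lapply(runs, `[[`, "best"))
  consensus <- apply(bests, 2, stats::median)
  ew <- list(...)$electrode_width
  if (is.null(ew)) ew <- 0.007
  dsep <- 2 * consensus[["gap_sense_drive_mm"]] + 2 * ew * 1000 +
    consensus[["gap_sense_sense_mm"]]
  structure(list(runs = runs, best_individuals = bests,
                 consensus = consensus, drive_separation_mm = dsep,
                 seeds = seeds),
            class = "ga_consensus")
}
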