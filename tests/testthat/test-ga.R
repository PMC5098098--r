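# Genetic-algorithm operators and the full loop on cheap fitnesses.

test_that("SUS always keeps the better of two individuals", {
  set.seed(1)
  for (i in 1:200) {
    idx <- stochastic_uniform_select(c(1, 2), 2)
    expect_true(1 %in% idx)  # rank-scaled expectation of the best > 1
  }
})

test_that("SUS with uniform fitness selects each individual exactly once",
{
  set.seed(2)
  for (i in 1:50) {
    idx <- stochastic_uniform_select(rep(3.5, 8), 8)
    expect_setequal(idx, 1:8)
  }
})

test_that("SUS selection frequencies match scaled expectations", {
  set.seed(3)
  fit <- c(0.1, 0.5, 1.0, 2.0, 10)
  n <- length(fit)
  counts <- numeric(n)
  draws <- 1e4
  for (i in seq_len(draws)) {
    idx <- stochastic_uniform_select(fit, n)
    counts <- counts + tabulate(idx, n)
  }
  scaled <- 1 / sqrt(rank(fit))
  expected <- n * scaled / sum(scaled)
  expect_true(all(abs(counts / draws - expected) / expected < 0.02))
})

test_that("arithmetic crossover is convex and degenerate-safe", {
  p1 <- c(10, 20, 5, 30); p2 <- c(80, 3, 33, 4)
  expect_equal(arithmetic_crossover(p1, p1), p1)
  expect_equal(arithmetic_crossover(p1, p2, lambda = 0.5), (p1 + p2) / 2)
  set.seed(4)
  for (i in 1:1000) {
    ch <- arithmetic_crossover(p1, p2)
    expect_true(all(ch >= pmin(p1, p2) - 1e-12 &
                      ch <= pmax(p1, p2) + 1e-12))
    # children lie on the segment: same lambda in every component
    lam <- (ch - p2) / (p1 - p2)
    expect_lt(diff(range(lam)), 1e-12)
  }
})

test_that("adaptive feasible mutation is bounded and identity at step 0",
{
  b <- default_ga_bounds()
  corner <- b[, 1]
  expect_identical(adaptive_feasible_mutation(corner, b, 0), corner)
  set.seed(5)
  for (i in 1:10000) {
    m <- adaptive_feasible_mutation(corner, b, 0.5)
    expect_true(all(m >= b[, 1] & m <= b[, 2]))
  }
})

test_that("step state contracts to its floor on a stalled run", {
  cfg <- ga_config(population_size = 10, max_generations = 12,
                   stall_generations = 50, seed = 11)
  res <- run_ga(function(x) 1, cfg)
  steps <- res$history$mutation_step
  expect_true(all(diff(steps[-1]) <= 1e-12))
  expect_equal(res$mutation_step, 0.02)  # documented floor
})

test_that("offspring accounting always sums to the population size", {
  for (N in c(10, 20, 100)) for (cf in c(0, 0.37, 0.8, 1)) {
    cfg <- ga_config(population_size = N, elite_count = 2,
                     crossover_fraction = cf)
    ct <- eimsim:::.offspring_counts(cfg)
    expect_equal(ct$elite + ct$cross + ct$mutant, N)
    expect_equal(ct$cross, round(cf * (N - 2)))
  }
})

test_that("GA minimizes a convex bowl to the box midpoint, monotonically
           and reproducibly, evaluating only feasible points", {
  cfg <- ga_config(population_size = 30, max_generations = 50,
                   stall_generations = 50, seed = 42)
  mid <- rowMeans(cfg$bounds)
  seen <- new.env(); seen$bad <- FALSE
  fit <- function(x) {
    if (any(x < cfg$bounds[, 1] - 1e-12 | x > cfg$bounds[, 2] + 1e-12))
      seen$bad <- TRUE
    sum((x - mid)^2)
  }
  res <- run_ga(fit, cfg)
  expect_false(seen$bad)
  rng <- cfg$bounds[, 2] - cfg$bounds[, 1]
  expect_true(all(abs(res$best - mid) / rng < 0.01))
  expect_true(all(diff(res$history$best_fitness) <= 1e-12))  # elitism
  res2 <- run_ga(fit, cfg)
  expect_identical(res$history, res2$history)
  # non-finite fitness is ranked worst, with a warning, not fatal
  cfg2 <- ga_config(population_size = 10, max_generations = 1,
                    stall_generations = 50, seed = 1)
  expect_warning(
    res3 <- run_ga(function(x) if (x[1] < 40) NaN else sum(x), cfg2),
    "non-finite")
  expect_true(is.finite(res3$best_fitness))
})

test_that("an individual maps to a placeable electrode configuration", {
  cfg <- individual_to_config(c(45, 10, 7, 33))
  expect_equal(cfg$gap_sense_drive, 0.033)
  expect_equal(cfg$angular_halfwidth_sense, 10)
  p <- place_electrodes(build_limb(), cfg)
  expect_length(p, 4)
})
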