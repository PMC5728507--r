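test_that("tvac and tviw hit their schedule endpoints and midpoints", {
  s <- pso_settings(max_iterations = 30)
  expect_equal(unname(tvac(0, s)), c(2.5, 0.5))
  expect_equal(unname(tvac(30, s)), c(0.5, 2.5))
  expect_equal(unname(tvac(15, s)), c(1.5, 1.5))
  expect_equal(tviw(0, s), 0.9)
  expect_equal(tviw(30, s), 0.4)
  expect_equal(tviw(15, s), 0.65)
  expect_error(tvac(31, s), "0..30")
  expect_error(tviw(-1, s), "0..30")
})

test_that("velocity update follows the canonical rule with capping", {
  # all attraction terms vanish when X = pbest = gbest and V = 0
  x <- c(0.5, 0.5)
  v <- update_velocity(x, c(0, 0), x, x, w = 0.7, c1 = 2, c2 = 2,
                       lower = c(0, 0), upper = c(1, 1))
  expect_equal(v, c(0, 0))

  # pure inertia when both coefficients are zero (cap disabled)
  v <- update_velocity(c(0.2), c(0.4), c(0.9), c(0.9), w = 1,
                       c1 = 1e-12, c2 = 1e-12, lower = 0, upper = 1,
                       velocity_cap_fraction = Inf)
  expect_equal(v, 0.4, tolerance = 1e-9)

  # hand evaluation: 0.5*1 + 2*0.5*2 + 2*0.5*4 = 6.5
  v <- update_velocity(position = 0, velocity = 1, pbest = 2, gbest = 4,
                       w = 0.5, c1 = 2, c2 = 2, lower = 0, upper = 1,
                       velocity_cap_fraction = Inf, r1 = 0.5, r2 = 0.5)
  expect_equal(v, 6.5)

  # the cap limits each component to the fraction of its range
  v <- update_velocity(position = 0, velocity = 1, pbest = 2, gbest = 4,
                       w = 0.5, c1 = 2, c2 = 2, lower = 0, upper = 1,
                       velocity_cap_fraction = 0.2, r1 = 0.5, r2 = 0.5)
  expect_equal(v, 0.2)

  expect_error(update_velocity(c(0, 0), 0, c(0, 0), c(0, 0), 1, 1, 1,
                               c(0, 0), c(1, 1)),
               "dimension")
})

test_that("position update adds velocity, clips, and zeroes clipped velocity", {
  expect_equal(update_position(c(0.4, 0.6), c(0, 0), c(0, 0), c(1, 1)),
               list(position = c(0.4, 0.6), velocity = c(0, 0)))
  moved <- update_position(0.5, 0.3, 0, 1)
  expect_equal(moved$position, 0.8)
  expect_equal(moved$velocity, 0.3)
  clipped <- update_position(0.9, 0.3, 0, 1)
  expect_equal(clipped$position, 1.0)
  expect_equal(clipped$velocity, 0)
})

test_that("run_pso keeps particles in the box and gbest monotone", {
  lower <- c(0, -1)
  upper <- c(1, 2)
  worst_violation <- 0
  spy_fitness <- function(x) {
    worst_violation <<- max(worst_violation,
                            max(lower - x), max(x - upper))
    -sum((x - c(0.3, 0.5))^2)
  }
  res <- run_pso(spy_fitness, lower, upper,
                 pso_settings(population_size = 10, max_iterations = 15,
                              seed = 4))
  expect_lte(worst_violation, 0)
  expect_true(all(diff(res$gbest_history) >= 0))
  expect_length(res$gbest_history, 16)
  expect_equal(res$gbest_score, max(res$pbest_scores))
  expect_equal(nrow(res$trace), 16)

  flat <- run_pso(function(x) 1, 0, 1,
                  pso_settings(population_size = 5, max_iterations = 5,
                               seed = 1))
  expect_equal(flat$gbest_history, rep(1, 6))
})

test_that("non-finite fitness is ranked as -Inf with a warning", {
  f <- function(x) if (x[1] > 0.5) NaN else x[1]
  expect_warning(
    res <- run_pso(f, 0, 1, pso_settings(population_size = 6,
                                         max_iterations = 4, seed = 2)),
    "non-finite")
  expect_true(is.finite(res$gbest_score))
  expect_true(all(diff(res$gbest_history) >= 0))
})

test_that("the swarm matches the grid-search oracle on a 1-D quadratic", {
  # independent oracle: exhaustive grid of 10001 points
  grid <- seq(0, 1, length.out = 10001)
  oracle <- grid[which.max(-(grid - 0.3)^2)]
  expect_equal(oracle, 0.3)

  hits <- 0L
  for (seed in 1:10) {
    res <- run_pso(function(x) -(x - 0.3)^2, 0, 1,
                   pso_settings(population_size = 20, max_iterations = 30,
                                seed = seed))
    hits <- hits + (abs(res$gbest_position - oracle) < 0.05)
  }
  expect_gte(hits, 9L)
})

test_that("the swarm beats equal-budget random sampling on the quadratic", {
  f <- function(x) -(x - 0.3)^2
  pso_best <- random_best <- numeric(10)
  for (seed in 1:10) {
    s <- pso_settings(population_size = 10, max_iterations = 12,
                      seed = seed)
    pso_best[seed] <- run_pso(f, 0, 1, s)$gbest_score
    draws <- pswarmnet:::with_seed(seed + 1000,
                                   runif(10 * 13))  # pop * (t_max + 1)
    random_best[seed] <- max(vapply(draws, f, numeric(1)))
  }
  expect_gte(stats::median(pso_best), stats::median(random_best))
})

test_that("search traces serialize with schedule columns", {
  res <- run_pso(function(x) -(x - 0.5)^2, 0, 1,
                 pso_settings(population_size = 5, max_iterations = 3,
                              seed = 1))
  path <- tempfile(fileext = ".csv")
  write_trace(res, path)
  trace <- read.csv(path)
  expect_equal(names(trace),
               c("t", "w", "c1", "c2", "gbest_score", "mean_score",
                 "sd_score"))
  expect_equal(trace$w, c(0.9, 0.9 - 0.5/3, 0.9 - 1/3, 0.4),
               tolerance = 1e-12)
})
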