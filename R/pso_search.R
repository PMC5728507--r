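# Particle swarm optimizer over a bounded real box with time-varying
# acceleration coefficients (TVAC) and inertia weight (TVIW), velocity
# capping, box clipping, and pbest/gbest bookkeeping.  Maximization
# convention throughout.

#' Particle swarm optimizer settings
#'
#' The cognitive coefficient C1 moves linearly from `c1_initial` to
#' `c1_final` and the social coefficient C2 from `c2_initial` to `c2_final`
#' over the generations, while the inertia weight decreases linearly from
#' `w_max` to `w_min`.  The defaults are the classic TVAC/TVIW
#' recommendation: C1 2.5 -> 0.5, C2 0.5 -> 2.5, W 0.9 -> 0.4, which starts
#' the swarm exploring globally and ends it refining locally.
#'
#' @param population_size Number of particles (>= 2).
#' @param max_iterations Number of update generations t_max (>= 1).  The
#'   swarm is evaluated at generations 0..t_max, so a run performs
#'   `population_size * (max_iterations + 1)` fitness evaluations.
#' @param c1_initial,c1_final,c2_initial,c2_final Positive acceleration
#'   coefficient endpoints.
#' @param w_max,w_min Inertia weight endpoints, `w_max >= w_min`.
#' @param velocity_cap_fraction Each velocity component is capped at this
#'   fraction of its dimension's box range, in (0, 1].
#' @param seed Integer seed for position initialization and the R1/R2 draws.
#' @return An object of class `pso_settings`.
#' @export
pso_settings <- function(population_size = 20L, max_iterations = 30L,
                         c1_initial = 2.5, c1_final = 0.5,
                         c2_initial = 0.5, c2_final = 2.5,
                         w_max = 0.9, w_min = 0.4,
                         velocity_cap_fraction = 0.2, seed = 1L) {
  population_size <- as.integer(population_size)
  max_iterations <- as.integer(max_iterations)
  if (population_size < 2L) stop("'population_size' must be >= 2",
                                 call. = FALSE)
  if (max_iterations < 1L) stop("'max_iterations' must be >= 1",
                                call. = FALSE)
  for (nm in c("c1_initial", "c1_final", "c2_initial", "c2_final")) {
    v <- get(nm)
    stopifnot_scalar_number(v, nm)
    if (v <= 0) stop(sprintf("'%s' must be positive", nm), call. = FALSE)
  }
  stopifnot_scalar_number(w_max, "w_max")
  stopifnot_scalar_number(w_min, "w_min")
  if (w_max < w_min) stop("'w_max' must be >= 'w_min'", call. = FALSE)
  stopifnot_scalar_number(velocity_cap_fraction, "velocity_cap_fraction")
  if (velocity_cap_fraction <= 0 || velocity_cap_fraction > 1) {
    stop("'velocity_cap_fraction' must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(population_size = population_size, max_iterations = max_iterations,
         c1_initial = c1_initial, c1_final = c1_final,
         c2_initial = c2_initial, c2_final = c2_final,
         w_max = w_max, w_min = w_min,
         velocity_cap_fraction = velocity_cap_fraction,
         seed = as.integer(seed)),
    class = "pso_settings"
  )
}

check_generation <- function(t, settings) {
  stopifnot(inherits(settings, "pso_settings"))
  if (!is.numeric(t) || length(t) != 1L || t < 0 ||
      t > settings$max_iterations) {
    stop(sprintf("generation index must lie in 0..%d",
                 settings$max_iterations), call. = FALSE)
  }
  invisible(t)
}

#' Time-varying acceleration coefficients
#'
#' Linear schedules `C1 = C1i + (t/t_max) (C1f - C1i)` and
#' `C2 = C2i + (t/t_max) (C2f - C2i)`.
#'
#' @param t Generation index in 0..t_max.
#' @param settings A [pso_settings()] object.
#' @return Named numeric vector `c(c1 = ..., c2 = ...)`.
#' @examples
#' s <- pso_settings()
#' tvac(0, s)                   # c1 = 2.5, c2 = 0.5
#' tvac(s$max_iterations, s)    # c1 = 0.5, c2 = 2.5
#' @export
tvac <- function(t, settings) {
  check_generation(t, settings)
  frac <- t / settings$max_iterations
  c(c1 = settings$c1_initial + frac * (settings$c1_final - settings$c1_initial),
    c2 = settings$c2_initial + frac * (settings$c2_final - settings$c2_initial))
}

#' Time-varying inertia weight
#'
#' Linearly decreasing schedule `W = W_max - (t/t_max) (W_max - W_min)`.
#'
#' @inheritParams tvac
#' @return The inertia weight at generation `t`.
#' @examples
#' tviw(0, pso_settings())   # 0.9
#' @export
tviw <- function(t, settings) {
  check_generation(t, settings)
  settings$w_max - (t / settings$max_iterations) *
    (settings$w_max - settings$w_min)
}

#' Particle velocity update
#'
#' Canonical update
#' `V'(i) = W V(i) + C1 R1(i) (pbest(i) - X(i)) + C2 R2(i) (gbest(i) - X(i))`
#' with R1, R2 drawn independently per dimension on [0, 1], followed by a
#' per-dimension cap at `velocity_cap_fraction * (upper - lower)`.
#'
#' @param position,velocity,pbest,gbest Numeric vectors of equal length m.
#' @param w,c1,c2 Inertia weight and acceleration coefficients.
#' @param lower,upper Box bounds (length m) used for the cap.
#' @param velocity_cap_fraction Cap fraction in (0, 1]; `Inf` disables it.
#' @param r1,r2 Optional fixed random factors (length 1 or m); when `NULL`
#'   they are drawn from the current RNG stream.
#' @return The new velocity vector.
#' @export
update_velocity <- function(position, velocity, pbest, gbest, w, c1, c2,
                            lower, upper, velocity_cap_fraction = 0.2,
                            r1 = NULL, r2 = NULL) {
  m <- length(position)
  if (length(velocity) != m || length(pbest) != m || length(gbest) != m) {
    stop("position, velocity, pbest, gbest must share one dimension m",
         call. = FALSE)
  }
  if (is.null(r1)) r1 <- stats::runif(m)
  if (is.null(r2)) r2 <- stats::runif(m)
  v <- w * velocity + c1 * r1 * (pbest - position) +
    c2 * r2 * (gbest - position)
  if (is.finite(velocity_cap_fraction)) {
    cap <- velocity_cap_fraction * (upper - lower)
    v <- pmin(pmax(v, -cap), cap)
  }
  v
}

#' Particle position update
#'
#' `X' = X + V'`, clipped to the box; any clipped dimension has its velocity
#' component zeroed so the particle does not keep pushing into the wall.
#'
#' @param position,velocity Numeric vectors of equal length.
#' @param lower,upper Box bounds.
#' @return A list with the clipped `position` and adjusted `velocity`.
#' @export
update_position <- function(position, velocity, lower, upper) {
  x <- position + velocity
  clipped_lo <- x < lower
  clipped_hi <- x > upper
  x[clipped_lo] <- lower[clipped_lo]
  x[clipped_hi] <- upper[clipped_hi]
  velocity[clipped_lo | clipped_hi] <- 0
  list(position = x, velocity = velocity)
}

#' Run the particle swarm search
#'
#' Positions are initialized uniformly inside the box and velocities at
#' zero.  At each generation 0..t_max the whole swarm is scored, personal
#' bests and the global best are updated (strict improvement only, so the
#' earlier incumbent is kept on ties), and — except after the final
#' generation — the TVAC/TVIW schedules at t drive the velocity and position
#' updates.  Non-finite fitness values are treated as `-Inf` for ranking.
#'
#' @param fitness Objective to maximize.  By default a function of one
#'   position vector returning a scalar; with `vectorized = TRUE`, a
#'   function of the full population matrix (particles x m) returning one
#'   score per row (used to evaluate a swarm of network configurations in
#'   one call).
#' @param lower,upper Numeric box bounds of length m.
#' @param settings A [pso_settings()] object.
#' @param vectorized Whether `fitness` takes the population matrix.
#' @return An object of class `pso_result`: `gbest_position`, `gbest_score`,
#'   `pbest_positions` (list, one per particle), `pbest_scores`,
#'   `gbest_history` (length t_max + 1, non-decreasing), and `trace`, a data
#'   frame with one row per generation (t, w, c1, c2, gbest_score,
#'   mean_score, sd_score) suitable for fitness-curve plots.
#' @examples
#' res <- run_pso(function(x) -(x - 0.3)^2, 0, 1,
#'                pso_settings(max_iterations = 10, seed = 1))
#' res$gbest_position
#' @export
run_pso <- function(fitness, lower, upper, settings = pso_settings(),
                    vectorized = FALSE) {
  stopifnot(inherits(settings, "pso_settings"))
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != length(upper) || any(!is.finite(lower)) ||
      any(!is.finite(upper)) || any(lower > upper)) {
    stop("'lower' and 'upper' must be finite bounds with lower <= upper",
         call. = FALSE)
  }
  m <- length(lower)
  pop <- settings$population_size
  t_max <- settings$max_iterations

  n_nonfinite <- 0L
  score_all <- function(positions) {
    scores <- if (vectorized) {
      as.numeric(fitness(positions))
    } else {
      vapply(seq_len(nrow(positions)),
             function(i) as.numeric(fitness(positions[i, ]))[1L],
             numeric(1))
    }
    if (length(scores) != nrow(positions)) {
      stop("fitness must return one score per particle", call. = FALSE)
    }
    bad <- !is.finite(scores)
    if (any(bad)) {
      n_nonfinite <<- n_nonfinite + sum(bad)
      scores[bad] <- -Inf
    }
    scores
  }

  with_seed(settings$seed, {
    positions <- matrix(stats::runif(pop * m, rep(lower, each = pop),
                                     rep(upper, each = pop)),
                        nrow = pop, ncol = m)
    velocities <- matrix(0, nrow = pop, ncol = m)
    pbest_positions <- positions
    pbest_scores <- rep(-Inf, pop)
    gbest_position <- positions[1L, ]
    gbest_score <- -Inf
    gbest_history <- numeric(t_max + 1L)
    trace <- data.frame(t = 0:t_max, w = NA_real_, c1 = NA_real_,
                        c2 = NA_real_, gbest_score = NA_real_,
                        mean_score = NA_real_, sd_score = NA_real_)

    for (t in 0:t_max) {
      scores <- score_all(positions)
      improved <- scores > pbest_scores
      pbest_scores[improved] <- scores[improved]
      pbest_positions[improved, ] <- positions[improved, , drop = FALSE]
      best_i <- which.max(pbest_scores)
      if (pbest_scores[best_i] > gbest_score) {
        gbest_score <- pbest_scores[best_i]
        gbest_position <- pbest_positions[best_i, ]
      }
      gbest_history[t + 1L] <- gbest_score

      sched <- tvac(t, settings)
      w <- tviw(t, settings)
      finite <- scores[is.finite(scores)]
      trace[t + 1L, -1L] <- c(w, sched[["c1"]], sched[["c2"]], gbest_score,
                              if (length(finite)) mean(finite) else NA_real_,
                              if (length(finite) > 1L) stats::sd(finite)
                              else NA_real_)

      if (t < t_max) {
        for (i in seq_len(pop)) {
          v <- update_velocity(positions[i, ], velocities[i, ],
                               pbest_positions[i, ], gbest_position,
                               w, sched[["c1"]], sched[["c2"]],
                               lower, upper,
                               settings$velocity_cap_fraction)
          moved <- update_position(positions[i, ], v, lower, upper)
          positions[i, ] <- moved$position
          velocities[i, ] <- moved$velocity
        }
      }
    }

    if (n_nonfinite > 0L) {
      warning(sprintf(
        "%d fitness evaluation(s) returned non-finite values; scored -Inf",
        n_nonfinite), call. = FALSE)
    }
    structure(
      list(gbest_position = gbest_position, gbest_score = gbest_score,
           pbest_positions = lapply(seq_len(pop),
                                    function(i) pbest_positions[i, ]),
           pbest_scores = pbest_scores,
           gbest_history = gbest_history,
           trace = trace,
           settings = settings, lower = lower, upper = upper),
      class = "pso_result"
    )
  })
}

#' @export
print.pso_result <- function(x, ...) {
  cat(sprintf(
    "PSO search: %d particles, %d generations; gbest score %.6g\n",
    x$settings$population_size, x$settings$max_iterations, x$gbest_score))
  invisible(x)
}

#' Write a per-generation search trace as CSV
#'
#' One row per generation with the schedule values and swarm score summary,
#' the raw material for fitness-curve plots.
#'
#' @param result A [run_pso()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(result, path) {
  stopifnot(inherits(result, "pso_result"))
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}
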