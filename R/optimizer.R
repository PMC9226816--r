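# Particle swarm optimization over the (sKs, sKr, sK1) conductance-multiplier
# box: find combinations that prolong APD to a goal at the long BCL while
# maximizing positive rate dependence (minimizing dAPD_long - dAPD_short).

#' Swarm configuration
#'
#' Canonical PSO hyperparameters. Defaults are the Clerc-Kennedy
#' constriction-equivalent values: inertia `w = 0.7298`, cognitive and social
#' weights `c1 = c2 = 1.49618`.
#'
#' @param n_particles swarm size (>= 5).
#' @param n_iterations number of velocity/position updates.
#' @param w inertia weight.
#' @param c1,c2 cognitive and social acceleration weights.
#' @param seed random seed governing swarm initialization and updates; the
#'   simulation itself is deterministic.
#' @return a list of class `swarm_config`.
#' @export
swarm_config <- function(n_particles = 20, n_iterations = 60, w = 0.7298,
                         c1 = 1.49618, c2 = 1.49618, seed = 1L) {
  stopifnot(n_particles >= 5, n_iterations >= 1, w > 0, c1 > 0, c2 > 0)
  structure(list(n_particles = as.integer(n_particles),
                 n_iterations = as.integer(n_iterations),
                 w = w, c1 = c1, c2 = c2, seed = as.integer(seed)),
            class = "swarm_config")
}

#' Objective specification for the conductance search
#'
#' The objective is `(dAPD_long - dAPD_short) + lambda * max(0,
#' |APD_long - apd_goal| - goal_tolerance)`: minimizing it drives the search
#' toward combinations that hit the APD goal at the long BCL while prolonging
#' more at the short BCL (positive rate dependence). Loss of 1:1 capture,
#' repolarization failure or alternans at either BCL returns
#' `failure_penalty`.
#'
#' @param apd_goal target steady-state APD90 at `bcl_long`, ms (the search
#'   only prolongs, so this should exceed the control APD).
#' @param bcl_long,bcl_short reference cycle lengths, ms.
#' @param goal_tolerance slack on the APD goal before the penalty applies, ms.
#' @param lambda penalty weight per ms of goal miss; 10 makes the goal bind
#'   while leaving the rate-dependence term decisive near the goal surface.
#' @param failure_penalty objective value for failed simulations.
#' @param minutes pacing length per evaluation, simulated minutes; either a
#'   single value or `c(long, short)` to pace the two reference BCLs for
#'   different lengths (useful with `warm_start`, where the long-BCL goal
#'   surface needs more settling than the short-BCL side).
#' @param dt integration step, ms.
#' @param warm_start evaluate interventions by shortened pacing started from
#'   the control steady state at each BCL (which is always paced the full 16
#'   minutes, once, and cached). This removes most of the slow ionic drift
#'   from shortened evaluations and is the documented scaled-down search
#'   mode; final optima should still be re-scored at `minutes = 16`.
#' @return a list of class `objective_spec`.
#' @export
objective_spec <- function(apd_goal, bcl_long = 3000, bcl_short = 400,
                           goal_tolerance = 0, lambda = 10,
                           failure_penalty = 1e4, minutes = 16, dt = 0.02,
                           warm_start = FALSE) {
  stopifnot(is.finite(apd_goal), apd_goal > 0, bcl_long > bcl_short,
            goal_tolerance >= 0, lambda > 0, length(minutes) %in% 1:2,
            all(minutes > 0))
  minutes <- rep(minutes, length.out = 2)
  structure(list(apd_goal = apd_goal, bcl_long = bcl_long,
                 bcl_short = bcl_short, goal_tolerance = goal_tolerance,
                 lambda = lambda, failure_penalty = failure_penalty,
                 minutes = minutes, dt = dt, warm_start = isTRUE(warm_start)),
            class = "objective_spec")
}

#' Conductance-search objective
#'
#' Runs steady-state pacing at the long and short BCL for the multiplier
#' triple (memoised: multipliers are rounded to 3 decimals for the cache key)
#' and evaluates the rate-dependence objective of [objective_spec()].
#'
#' @param multipliers numeric triple `(sKs, sKr, sK1)`.
#' @param spec an [objective_spec()].
#' @param details return the component APDs alongside the value.
#' @return the scalar objective, or (with `details = TRUE`) a list with
#'   `value`, `apd_long`, `apd_short`, `delta_long`, `delta_short`,
#'   `rd_index`.
#' @export
ap_objective <- function(multipliers, spec, details = FALSE) {
  stopifnot(inherits(spec, "objective_spec"), length(multipliers) == 3)
  params <- scaled_params(multipliers[[1]], multipliers[[2]], multipliers[[3]])
  ctl <- scaled_params()
  runs <- if (spec$warm_start) {
    sl <- .control_steady(spec$bcl_long, spec$dt)
    ss <- .control_steady(spec$bcl_short, spec$dt)
    list(
      il = .apd_at(params, spec$bcl_long, spec$minutes[1], spec$dt,
                   init_state = sl$final_state, tag = "w"),
      is = .apd_at(params, spec$bcl_short, spec$minutes[2], spec$dt,
                   init_state = ss$final_state, tag = "w"),
      cl = sl, cs = ss)
  } else {
    list(
      il = .apd_at(params, spec$bcl_long, spec$minutes[1], spec$dt),
      is = .apd_at(params, spec$bcl_short, spec$minutes[2], spec$dt),
      cl = .apd_at(ctl, spec$bcl_long, spec$minutes[1], spec$dt),
      cs = .apd_at(ctl, spec$bcl_short, spec$minutes[2], spec$dt))
  }
  # the alternans flag compares the last two beats and is meaningless on the
  # short warm-started transients, so it gates full-length evaluations only
  ok <- vapply(runs, function(r)
    isTRUE(r$captured) && !isTRUE(r$repol_fail) &&
      (spec$warm_start || !isTRUE(r$alternans)) &&
      is.finite(r$apd90), logical(1))
  if (!all(ok)) {
    if (!details) return(spec$failure_penalty)
    return(list(value = spec$failure_penalty, apd_long = NA_real_,
                apd_short = NA_real_, delta_long = NA_real_,
                delta_short = NA_real_, rd_index = NA_real_))
  }
  dl <- runs$il$apd90 - runs$cl$apd90
  ds <- runs$is$apd90 - runs$cs$apd90
  miss <- max(0, abs(runs$il$apd90 - spec$apd_goal) - spec$goal_tolerance)
  val <- (dl - ds) + spec$lambda * miss
  if (!details) return(val)
  list(value = val, apd_long = runs$il$apd90, apd_short = runs$is$apd90,
       delta_long = dl, delta_short = ds, rd_index = ds - dl)
}

#' Particle swarm minimization
#'
#' Canonical PSO (velocity `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest -
#' x)`, positions clamped to the bounds). The global best is monotone
#' non-increasing over iterations and the whole run is reproducible for a
#' fixed seed.
#'
#' @param fn objective function of a numeric vector.
#' @param lower,upper per-dimension bounds.
#' @param config a [swarm_config()].
#' @param init optional matrix of starting positions (one row per particle);
#'   rows replace the first random particles after clamping to the bounds.
#'   Used for coarse-to-fine searches seeded from a grid scan, which makes
#'   small test-budget swarms reliable on the multimodal goal-penalty
#'   landscape; the default full-size search needs no seeding.
#' @return list with `par`, `value`, `gbest_trace` (best objective after
#'   initialization and after each iteration) and `n_evaluations`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' fit <- pso_minimize(sphere, rep(-5, 3), rep(5, 3),
#'                     swarm_config(n_particles = 20, n_iterations = 50))
#' fit$value
#' @export
pso_minimize <- function(fn, lower, upper, config = swarm_config(),
                         init = NULL) {
  stopifnot(inherits(config, "swarm_config"),
            length(lower) == length(upper), all(upper > lower))
  d <- length(lower)
  np <- config$n_particles

  # localize RNG state
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  rng <- upper - lower
  x <- matrix(runif(np * d, rep(lower, each = np), rep(upper, each = np)),
              nrow = np)
  v <- matrix(runif(np * d, rep(-rng / 2, each = np), rep(rng / 2, each = np)),
              nrow = np)
  if (!is.null(init)) {
    init <- matrix(as.numeric(init), ncol = d)
    k <- min(nrow(init), np)
    for (i in seq_len(k))
      x[i, ] <- pmin(pmax(init[i, ], lower), upper)
  }
  f <- apply(x, 1, fn)
  n_eval <- np
  pbest <- x; pbest_f <- f
  g <- which.min(f)
  gbest <- x[g, ]; gbest_f <- f[g]
  trace <- numeric(config$n_iterations + 1)
  trace[1] <- gbest_f

  for (it in seq_len(config$n_iterations)) {
    for (i in seq_len(np)) {
      r1 <- runif(d); r2 <- runif(d)
      v[i, ] <- config$w * v[i, ] + config$c1 * r1 * (pbest[i, ] - x[i, ]) +
        config$c2 * r2 * (gbest - x[i, ])
      v[i, ] <- pmin(pmax(v[i, ], -rng), rng)
      x[i, ] <- pmin(pmax(x[i, ] + v[i, ], lower), upper)
      fi <- fn(x[i, ])
      n_eval <- n_eval + 1
      if (fi < pbest_f[i]) { pbest[i, ] <- x[i, ]; pbest_f[i] <- fi }
      if (fi < gbest_f) { gbest <- x[i, ]; gbest_f <- fi }
    }
    trace[it + 1] <- gbest_f
  }
  if (!is.finite(gbest_f))
    stop("optimization failure: no finite objective value found")
  list(par = gbest, value = gbest_f, gbest_trace = trace,
       n_evaluations = n_eval)
}

#' Search for conductance combinations prolonging APD with positive rate
#' dependence
#'
#' Runs [pso_minimize()] over the `(sKs, sKr, sK1)` box for a given APD goal.
#' The lower bound on sK1 is the protocol knob: raising it from 0.2 toward 1
#' restricts IK1 block and trades positive rate dependence for repolarization
#' reserve.
#'
#' @param apd_goal target APD90 at the long BCL, ms.
#' @param k1_min lower bound on sK1 (protocols: 0.2, 0.5, 0.7, 1.0).
#' @param ks_bounds,kr_bounds bounds for sKs and sKr (default `c(0, 2)`).
#' @param k1_max upper bound on sK1 (default 2).
#' @param config a [swarm_config()].
#' @param spec an [objective_spec()]; built from `apd_goal` if missing.
#' @param init optional seeding positions, passed to [pso_minimize()].
#' @param ... passed to [objective_spec()] when `spec` is missing.
#' @return list with `par` (named multipliers), `value`, `gbest_trace`,
#'   `details` (APDs and rd_index at the optimum) and the settings used.
#' @export
optimize_conductances <- function(apd_goal, k1_min = 0.2,
                                  ks_bounds = c(0, 2), kr_bounds = c(0, 2),
                                  k1_max = 2, config = swarm_config(),
                                  spec = NULL, init = NULL, ...) {
  if (is.null(spec)) spec <- objective_spec(apd_goal, ...)
  lower <- c(ks_bounds[1], kr_bounds[1], k1_min)
  upper <- c(ks_bounds[2], kr_bounds[2], k1_max)
  fit <- pso_minimize(function(m) ap_objective(m, spec), lower, upper, config,
                      init = init)
  if (fit$value >= spec$failure_penalty)
    stop("optimization failure: every evaluation failed (capture loss?)")
  par <- setNames(fit$par, c("sKs", "sKr", "sK1"))
  list(par = par, value = fit$value, gbest_trace = fit$gbest_trace,
       n_evaluations = fit$n_evaluations,
       details = ap_objective(par, spec, details = TRUE),
       apd_goal = spec$apd_goal, k1_min = k1_min, spec = spec,
       config = config)
}
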