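# Particle swarm optimizer and the conductance-search objective.

test_that("PSO finds the sphere optimum and gbest is monotone", {
  sphere <- function(x) sum(x^2)
  fit <- pso_minimize(sphere, rep(-5, 3), rep(5, 3),
                      swarm_config(n_particles = 30, n_iterations = 100,
                                   seed = 7))
  expect_true(all(abs(fit$par) < 1e-2))
  expect_lt(fit$value, 1e-3)
  expect_true(all(diff(fit$gbest_trace) <= 0))
  expect_length(fit$gbest_trace, 101)
})

test_that("PSO is reproducible for a fixed seed and respects bounds", {
  rosen <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  cfg <- swarm_config(n_particles = 12, n_iterations = 40, seed = 11)
  f1 <- pso_minimize(rosen, c(-2, -2), c(2, 2), cfg)
  f2 <- pso_minimize(rosen, c(-2, -2), c(2, 2), cfg)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$gbest_trace, f2$gbest_trace)
  lo <- c(0.5, 0.5)
  f3 <- pso_minimize(rosen, lo, c(2, 2), cfg)
  expect_true(all(f3$par >= lo - 1e-12))
  # PSO must not disturb the caller's RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(pso_minimize(rosen, c(-2, -2), c(2, 2), cfg))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("swarm and objective specifications are validated", {
  expect_error(swarm_config(n_particles = 3), "n_particles")
  expect_error(objective_spec(-10), "apd_goal")
  expect_error(objective_spec(330, bcl_long = 300, bcl_short = 400))
})

test_that("the conductance objective matches its formula on cached runs", {
  # scaled pacing keeps this cheap; the objective must equal the direct
  # recomputation from the same steady-state APDs
  spec <- objective_spec(300, minutes = 0.5)
  ctl <- restitution(scaled_params(), bcls = c(400, 3000), minutes = 0.5)
  m <- c(1.5, 0.6, 0.5)
  iv <- restitution(scaled_params(m[1], m[2], m[3]), bcls = c(400, 3000),
                    minutes = 0.5)
  dl <- iv$apd90[2] - ctl$apd90[2]
  ds <- iv$apd90[1] - ctl$apd90[1]
  want <- (dl - ds) + spec$lambda * abs(iv$apd90[2] - spec$apd_goal)
  expect_equal(ap_objective(m, spec), want, tolerance = 1e-10)
  det <- ap_objective(m, spec, details = TRUE)
  expect_equal(det$value, want, tolerance = 1e-10)
  expect_equal(det$rd_index, ds - dl, tolerance = 1e-10)
  # control multipliers with the goal at the control APD give exactly zero
  spec0 <- objective_spec(ctl$apd90[2], minutes = 0.5)
  expect_equal(ap_objective(c(1, 1, 1), spec0), 0, tolerance = 1e-10)
})
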