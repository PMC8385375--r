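test_that("a stop at time zero degenerates to the stable environment", {
  p <- baseline()
  tt <- seq(0, 10, by = 0.1)
  for (resume in c("continue", "restart")) {
    env <- dd_environment("gaussian_stop", stop_time = 0, resume = resume)
    expect_equal(alpha_env(tt, env, p), alpha_at(tt, p))
  }
})

test_that("no repair is possible while the damage source is active", {
  p <- baseline()
  before <- seq(0, 2.49, by = 0.01)
  envs <- list(
    dd_environment("gaussian_stop", stop_time = 2.5),
    dd_environment("gaussian_stop", stop_time = 2.5, resume = "restart"),
    dd_environment("exponential_stop", stop_time = 2.5),
    dd_environment("uniform_stop_fading", stop_time = 2.5))
  for (env in envs)
    expect_true(all(alpha_env(before, env, p) == 0))
})

test_that("resume modes: original clock vs restarted window; fading scales the height", {
  p <- baseline()
  tau <- 2
  cont <- dd_environment("gaussian_stop", stop_time = tau)
  rest <- dd_environment("gaussian_stop", stop_time = tau, resume = "restart")
  after <- seq(tau, tau + 5, by = 0.05)
  expect_equal(alpha_env(after, cont, p), alpha_at(after, p))
  expect_equal(alpha_env(after, rest, p), alpha_at(after - tau, p))
  # zero fade coincides with the restarted window
  fade0 <- dd_environment("uniform_stop_fading", stop_time = tau, fade = 0)
  expect_equal(alpha_env(after, fade0, p), alpha_env(after, rest, p))
  # positive fade scales the whole window by exp(-fade * tau)
  fade <- dd_environment("uniform_stop_fading", stop_time = tau, fade = 0.3)
  expect_equal(alpha_env(after, fade, p),
               exp(-0.3 * tau) * alpha_env(after, rest, p))
})

test_that("fluctuating environments demand a realised stop time", {
  p <- baseline()
  env <- dd_environment("gaussian_stop")
  expect_error(alpha_env(1, env, p), "stop time")
  expect_error(run_ode(p, env = env), "stop time")
  expect_error(run_stochastic(p, seed = 1, env = env), "stop time")
})

test_that("invalid stop-time laws are rejected", {
  expect_error(dd_environment("gaussian_stop", variance = 0), "variance")
  expect_error(dd_environment("exponential_stop", rate = -1), "rate")
  expect_error(dd_environment("uniform_stop_fading", lower = 2, upper = 1),
               "lower")
  expect_error(dd_environment("gaussian_stop", stop_time = -1), "stop_time")
})

test_that("quadrature ensembles are normalised and match truncated-normal moments", {
  ens <- gaussian_ensemble(n_nodes = 200)
  w <- ens$nodes$weight
  expect_lt(abs(sum(w) - 1), 1e-10)
  expect_true(all(w >= 0))
  expect_true(all(ens$nodes$tau >= 0))
  # closed-form mean of a Normal(1.7, 1.5^2) truncated to [0, Inf)
  z <- (0 - 1.7) / 1.5
  m_trunc <- 1.7 + 1.5 * dnorm(z) / (1 - pnorm(z))
  expect_lt(abs(sum(w * ens$nodes$tau) - m_trunc), 1e-3)
})

test_that("a realised or stable environment collapses to a single node", {
  point <- build_ensemble(dd_environment("gaussian_stop", stop_time = 1.2))
  expect_equal(nrow(point$nodes), 1L)
  expect_equal(point$nodes$weight, 1)
  expect_equal(point$nodes$tau, 1.2)
  stable <- build_ensemble(dd_environment())
  expect_equal(nrow(stable$nodes), 1L)
})

test_that("Monte-Carlo ensembles are seeded, equal-weighted and RNG-clean", {
  env <- dd_environment("gaussian_stop")
  set.seed(321)
  before <- .Random.seed
  e1 <- build_ensemble(env, n_nodes = 100, method = "monte-carlo", seed = 5)
  expect_identical(.Random.seed, before)
  e2 <- build_ensemble(env, n_nodes = 100, method = "monte-carlo", seed = 5)
  expect_identical(e1$nodes, e2$nodes)
  expect_true(all(e1$nodes$weight == 1 / 100))
  expect_true(all(e1$nodes$tau >= 0))  # truncated draws
})

test_that("quadrature and Monte-Carlo estimates of the expected Ts agree", {
  p <- baseline()
  env <- dd_environment("gaussian_stop")
  quad <- expected_over_environment(p, build_ensemble(env, n_nodes = 60))
  mc_ens <- build_ensemble(env, n_nodes = 60, method = "monte-carlo",
                           seed = 17)
  mc <- expected_over_environment(p, mc_ens)
  mc_se <- sd(mc$nodes$value) / sqrt(nrow(mc$nodes))
  expect_lt(abs(quad$value - mc$value), 3 * mc_se)
})

test_that("gated solutions coincide with a repair-free run before the stop time", {
  p <- baseline()
  tau <- 2
  tg <- seq(0, tau, by = 0.1)
  gated <- run_ode(p, env = dd_environment("gaussian_stop", stop_time = tau),
                   times = tg, stop_at_saturation = FALSE, t_max = tau)
  free <- run_ode(baseline(alpha_m = 0), times = tg,
                  stop_at_saturation = FALSE, t_max = tau)
  expect_equal(gated$state, free$state, tolerance = 1e-7)
})

test_that("delaying the whole stop-time law does not shorten the expected Ts", {
  p <- baseline()
  e_early <- build_ensemble(dd_environment("gaussian_stop", mean = 1.7),
                            n_nodes = 40)
  e_late <- build_ensemble(dd_environment("gaussian_stop", mean = 2.7),
                           n_nodes = 40)
  ts_early <- expected_over_environment(p, e_early)$value
  ts_late <- expected_over_environment(p, e_late)$value
  expect_gte(ts_late, ts_early)
})

test_that("a single-node ensemble reduces to the plain run", {
  p <- baseline()
  env <- dd_environment("gaussian_stop", stop_time = 1.5)
  exp1 <- expected_over_environment(p, build_ensemble(env))
  expect_equal(exp1$value, run_ode(p, env = env)$Ts)
})

test_that("non-saturating environment weight is reported, bounded and fatal past half", {
  p <- baseline()
  ens <- gaussian_ensemble(n_nodes = 50)
  expect_warning(expected_over_environment(p, ens, t_max = 44), "excluding")
  expect_error(expected_over_environment(p, ens, t_max = 30), "weight")
})

test_that("ensemble-averaged trajectories reduce to the plain trajectory when stable", {
  p <- baseline()
  tg <- seq(0, 10, by = 0.5)
  avg <- average_trajectories(p, build_ensemble(dd_environment()),
                              times = tg)
  plain <- run_ode(p, times = tg, lineage = TRUE,
                   stop_at_saturation = FALSE)
  expect_equal(avg$t, tg)
  expect_equal(as.matrix(avg[, -1]), plain$state, tolerance = 1e-10)
})
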