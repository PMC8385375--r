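test_that("zero-rate transitions leave the population unchanged", {
  p <- baseline(gamma1 = 0, gamma_ad = 0, gamma_r = 0, delta = 0,
                alpha_m = 0, beta_m = 0)
  s <- population_state(D = 100, A = 7, R = 3)
  set.seed(1)
  out <- markov_step(s, p)
  expect_equal(out$D, 100)
  expect_equal(out$A, 7)
  expect_equal(out$R, 3)
  expect_equal(out$dead_cum, 0)
  expect_equal(out$step, 1L)
})

test_that("certain death empties the damaged compartment", {
  p <- baseline(gamma1 = 1, alpha_m = 0, beta_m = 0)
  set.seed(1)
  out <- markov_step(population_state(D = 100), p)
  expect_equal(out$D, 0)
  expect_equal(out$dead_cum, 100)
})

test_that("one-step means match the closed-form multinomial expectation", {
  p <- baseline()
  n_rep <- 300
  a1 <- alpha_at(1, p)                 # = alpha_m at baseline
  b1 <- beta_at(1, p)
  q_stay <- 1 - p$gamma1 - a1 - b1
  set.seed(42)
  draws <- t(vapply(seq_len(n_rep), function(i) {
    out <- markov_step(population_state(D = 10000), p)
    c(D = out$D, R = out$R)
  }, c(D = 0, R = 0)))
  se_D <- sqrt(10000 * q_stay * (1 - q_stay)) / sqrt(n_rep)
  se_R <- sqrt(10000 * a1 * (1 - a1)) / sqrt(n_rep)
  expect_lt(abs(mean(draws[, "D"]) - 10000 * q_stay), 3 * se_D)
  expect_lt(abs(mean(draws[, "R"]) - 10000 * a1), 3 * se_R)
})

test_that("division doubles when space allows and fills proportionally when not", {
  p <- baseline()
  s <- population_state(D = 0, A = 10, R = 10)
  out <- divide_step(s, p)
  expect_equal(c(out$A, out$R), c(20, 20))
  # free = 10 < demand = 20: equal demand splits the space equally
  p30 <- baseline(N0 = 10, Nmax = 30)
  out <- divide_step(population_state(D = 0, A = 10, R = 10), p30)
  expect_equal(c(out$A, out$R), c(15, 15))
  # largest-remainder rounding adds exactly `free` daughters
  p17 <- baseline(N0 = 10, Nmax = 17)
  out <- divide_step(population_state(D = 0, A = 7, R = 5), p17)
  expect_equal(out$A + out$R, 17)          # 5 free slots all used
  expect_equal(c(out$A, out$R), c(10, 7))  # 35/12 -> 3, 25/12 -> 2
  # nothing divides when there is nothing to divide
  out <- divide_step(population_state(D = 50), p)
  expect_equal(c(out$A, out$R), c(0, 0))
})

test_that("certain repair saturates at the hand-iterated doubling time", {
  p <- baseline(gamma1 = 0, alpha_m = 1, sigma = 1e6, beta_m = 0)
  run <- run_stochastic(p, seed = 3)
  expect_true(run$saturated)
  expect_equal(run$Ts, certain_repair_ts(p$N0, p$Nmax))
  expect_equal(run$Ts, 3L)
})

test_that("a closed repair channel never saturates and is flagged, not an error", {
  p <- baseline(alpha_m = 0, beta_m = 0, delta = 0)
  run <- run_stochastic(p, seed = 5, max_steps = 60)
  expect_false(run$saturated)
  expect_true(is.na(run$Ts))
  expect_error(mean_saturation_time(p, n_rep = 3, max_steps = 60),
               "no replicate saturated")
})

test_that("runs are reproducible from the seed and leave the caller RNG untouched", {
  p <- baseline()
  set.seed(999)
  before <- .Random.seed
  r1 <- run_stochastic(p, seed = 11)
  expect_identical(.Random.seed, before)
  r2 <- run_stochastic(p, seed = 11)
  r3 <- run_stochastic(p, seed = 12)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_false(identical(r1$trajectory, r3$trajectory))
})

test_that("per-step flows conserve cells and respect the capacity bound", {
  p <- baseline()
  for (seed in 1:3) {
    set.seed(seed)
    s <- population_state(D = p$N0)
    for (n in 1:25) {
      s2 <- markov_step(s, p)
      f <- s2$flows
      expect_equal(s$D, s2$D + f$D_died + f$D_adapted + f$D_repaired)
      expect_equal(s$A, (s2$A - f$D_adapted) + f$A_died + f$A_repaired)
      s3 <- divide_step(s2, p)
      expect_lte(s3$D + s3$A + s3$R, p$Nmax)
      s <- s3
    }
  }
})

test_that("with no repaired-cell death the healthy compartment never shrinks", {
  p <- baseline()   # gamma_r = 0
  for (seed in 4:6) {
    tr <- run_stochastic(p, seed = seed)$trajectory
    expect_true(all(diff(tr$R) >= 0))
    expect_true(all(diff(tr$D) <= 0))  # no re-damage
    expect_true(all(tr$D + tr$A + tr$R <= p$Nmax))
  }
})

test_that("mean saturation time averages replicates and shrinks its error as 1/n", {
  p <- baseline()
  one <- mean_saturation_time(p, n_rep = 1, base_seed = 41)
  expect_equal(one$mean, run_stochastic(p, seed = 42)$Ts)
  s100 <- mean_saturation_time(p, n_rep = 100, base_seed = 11)
  s400 <- mean_saturation_time(p, n_rep = 400, base_seed = 11)
  expect_lt(s400$se, s100$se)
  expect_gt(s100$se / s400$se, 1.5)  # ~2 for i.i.d. averaging
  expect_lt(s100$se / s400$se, 2.7)
})

test_that("saturation times concentrate at realistic population sizes", {
  p <- baseline()
  mt <- mean_saturation_time(p, n_rep = 200, base_seed = 7)
  expect_equal(mt$n_excluded, 0)
  expect_lt(mt$sd / mt$mean, 0.2)
})

test_that("the stochastic and continuous models agree on order of magnitude and optimum", {
  p <- baseline()
  ode_ts <- run_ode(p)$Ts
  mt <- mean_saturation_time(p, n_rep = 200, base_seed = 7)
  expect_gt(mt$mean / ode_ts, 0.5)
  expect_lt(mt$mean / ode_ts, 1.2)
  # argmin over mu_b within +-0.5 of the refined continuous optimum
  ode_opt <- sweep_mu_b(p, grid = seq(2.6, 3.8, by = 0.2))$argmin_refined
  grid <- c(1.5, 2.9, 3.4, 5.0, 6.5)
  means <- vapply(grid, function(m) {
    mean_saturation_time(baseline(mu_b = m), n_rep = 300,
                         base_seed = 100)$mean
  }, numeric(1))
  expect_lt(abs(grid[which.min(means)] - ode_opt), 0.5)
})
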