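test_that("extinction is a fixed point and the initial derivative matches the model", {
  p <- baseline()
  expect_equal(ode_rhs(0, c(0, 0, 0), p), c(0, 0, 0))
  expect_equal(ode_rhs(3, c(0, 0, 0, 0), p), c(0, 0, 0, 0))
  # hand evaluation at t = 0 from the printed curves
  a0 <- p$alpha_m * exp(-(0 - p$mu_a)^2 / p$sigma^2)
  b0 <- p$beta_m / (1 + exp(-p$p * (0 - p$mu_b)))
  d <- ode_rhs(0, c(p$N0, 0, 0), p)
  expect_equal(d[1], -p$N0 * (p$gamma1 + b0 + a0))
  expect_equal(d[2], b0 * p$N0)
  expect_equal(d[3], a0 * p$N0)
})

test_that("the lineage split is an exact refinement of the three-compartment model", {
  p <- baseline()
  # rhs level: Rd' + Ra' = R' for matched states
  y3 <- c(5000, 300, 20000)
  for (split in c(0, 0.3, 1)) {
    y4 <- c(y3[1], y3[2], (1 - split) * y3[3], split * y3[3])
    d3 <- ode_rhs(2.5, y3, p)
    d4 <- ode_rhs(2.5, y4, p)
    expect_equal(d4[1:2], d3[1:2])
    expect_equal(d4[3] + d4[4], d3[3], tolerance = 1e-12)
  }
  # trajectory level
  tg <- seq(0, 30, by = 0.5)
  r3 <- run_ode(p, times = tg, stop_at_saturation = FALSE)
  r4 <- run_ode(p, times = tg, lineage = TRUE, stop_at_saturation = FALSE)
  expect_lt(max(abs(r3$state[, "R"] -
                    (r4$state[, "Rd"] + r4$state[, "Ra"]))),
            1e-4 * p$Nmax)
  expect_lt(abs(run_ode(p)$Ts - run_ode(p, lineage = TRUE)$Ts), 1e-3)
})

test_that("saturation is detected by root finding at the one-cell criterion", {
  p <- baseline()
  run <- run_ode(p)
  expect_true(run$saturated)
  expect_lt(abs(run$final_state[["R"]] - (p$Nmax - 1)), 1e-2)
  # the output grid does not affect the located time beyond the tolerance
  # floor: |dR/dt| ~ 2 cells/step at the crossing and atol = 1e-3 cells
  run_g <- run_ode(p, times = seq(0, 100, by = 1))
  expect_lt(abs(run$Ts - run_g$Ts), 2e-3)
})

test_that("no saturation without a repair route; flagged, not an error", {
  r <- run_ode(baseline(alpha_m = 0, beta_m = 0, delta = 0), t_max = 100)
  expect_false(r$saturated)
  expect_true(is.na(r$Ts))
  expect_equal(r$final_state[["R"]], 0)
})

test_that("the dynamics are invariant under joint rescaling of N0 and Nmax", {
  # compartments scale exactly with (N0, Nmax); only the absolute one-cell
  # saturation criterion breaks the scaling, adding ~log(2)/decay-rate to Ts
  tg <- seq(0, 30, by = 1)
  r1 <- run_ode(baseline(), times = tg, stop_at_saturation = FALSE)
  r2 <- run_ode(baseline(N0 = 40000, Nmax = 200000), times = tg,
                stop_at_saturation = FALSE)
  expect_equal(2 * r1$state, r2$state, tolerance = 1e-6)
  t1 <- run_ode(baseline())$Ts
  t2 <- run_ode(baseline(N0 = 40000, Nmax = 200000))$Ts
  expect_gt(t2, t1)           # tighter relative criterion takes longer
  expect_lt(abs(t2 - t1), 3)  # but only by the tail-approach time
})

test_that("the saturation time is converged in the solver tolerances", {
  p <- baseline()
  t1 <- run_ode(p)$Ts
  t2 <- run_ode(p, rtol = 5e-9, atol = 5e-9 * p$Nmax)$Ts
  expect_lt(abs(t1 - t2), 1e-3)
})

test_that("solutions stay non-negative and healthy cells never decrease", {
  p <- baseline()
  tg <- seq(0, 40, by = 0.2)
  r <- run_ode(p, times = tg, lineage = TRUE, stop_at_saturation = FALSE)
  expect_gt(min(r$state), -1e-6 * p$Nmax)
  R <- r$state[, "Rd"] + r$state[, "Ra"]
  expect_true(all(diff(R) >= -1e-8 * p$Nmax))  # gamma_r = 0
})

test_that("the ancestry fraction isolates the two survival routes", {
  # no direct repair: adaptation is the sole route, fraction 1, slow recovery
  r_ad <- run_ode(baseline(alpha_m = 0), lineage = TRUE)
  expect_equal(structure_fraction(r_ad), 1)
  expect_gt(r_ad$Ts, run_ode(baseline(), lineage = TRUE)$Ts)
  # no adapted repair: fraction 0
  r_dir <- run_ode(baseline(delta = 0), lineage = TRUE)
  expect_equal(structure_fraction(r_dir), 0)
})

test_that("the ancestry fraction demands a saturated lineage run", {
  p <- baseline()
  expect_error(structure_fraction(run_ode(p)), "lineage")
  expect_error(
    structure_fraction(run_ode(p, lineage = TRUE, t_max = 5)),
    "did not saturate")
})
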