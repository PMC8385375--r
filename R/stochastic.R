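#' Population state of the stochastic model
#'
#' Compartment counts at a discrete step: damaged `D`, adapted `A`,
#' repaired (healthy) `R`, plus the cumulative death count. Cells are
#' simulated as compartment counts with multinomial draws — the same law as
#' an agent-per-cell simulation, orders of magnitude faster.
#'
#' @param D,A,R non-negative integer compartment counts.
#' @param step step index `n >= 0` (0 = the moment of damage).
#' @param dead_cum cumulative number of deaths up to `step`.
#' @return An object of class `dd_state`.
#' @seealso [markov_step()], [divide_step()], [run_stochastic()]
#' @export
population_state <- function(D, A = 0, R = 0, step = 0L, dead_cum = 0) {
  stopifnot(D >= 0, A >= 0, R >= 0, step >= 0,
            D == round(D), A == round(A), R == round(R))
  structure(list(step = as.integer(step), D = D, A = A, R = R,
                 dead_cum = dead_cum, flows = NULL),
            class = "dd_state")
}

#' @export
print.dd_state <- function(x, ...) {
  cat(sprintf("step %d: D = %g, A = %g, R = %g (cumulative deaths %g)\n",
              x$step, x$D, x$A, x$R, x$dead_cum))
  invisible(x)
}

#' One transition step of the stochastic model
#'
#' Advances the population by one Markov transition at step `n = step + 1`.
#' Each damaged cell takes exactly one of four exclusive fates in a single
#' multinomial draw: death (probability `gamma1`), adaptation (`beta(n)`),
#' repair (`alpha(n)`, environment-gated), or remaining damaged. Each
#' adapted cell dies (`gamma_ad`), repairs (`delta`) or remains adapted;
#' repaired cells die with probability `gamma_r` (zero at baseline). The
#' returned state is post-transition and pre-division; division is a
#' separate step ([divide_step()]) applied at the end of each step.
#'
#' Uses R's global random number stream; seed control belongs to the caller
#' (see [run_stochastic()]).
#'
#' @param state a [population_state()].
#' @param params a [dd_params()] object.
#' @param env a (realised) [dd_environment()].
#' @return The new `dd_state`, with a `flows` field recording the per-step
#'   transition counts (for conservation book-keeping).
#' @export
markov_step <- function(state, params, env = dd_environment()) {
  n <- state$step + 1L
  a <- alpha_env(n, env, params)
  b <- beta_at(n, params)
  p_rest <- 1 - params$gamma1 - b - a
  if (p_rest < -1e-9)
    stop(sprintf("fate probabilities exceed 1 at step %d: %.6g", n,
                 params$gamma1 + a + b), call. = FALSE)
  p_rest <- max(p_rest, 0)

  if (state$D > 0) {
    dd <- stats::rmultinom(1, state$D, c(params$gamma1, b, a, p_rest))[, 1]
  } else {
    dd <- c(0, 0, 0, 0)
  }
  if (state$A > 0) {
    aa <- stats::rmultinom(1, state$A,
                           c(params$gamma_ad, params$delta,
                             1 - params$gamma_ad - params$delta))[, 1]
  } else {
    aa <- c(0, 0, 0)
  }
  r_died <- if (state$R > 0 && params$gamma_r > 0)
    stats::rbinom(1, state$R, params$gamma_r) else 0

  out <- population_state(D = dd[4],
                          A = state$A - aa[1] - aa[2] + dd[2],
                          R = state$R - r_died + dd[3] + aa[2],
                          step = n,
                          dead_cum = state$dead_cum + dd[1] + aa[1] + r_died)
  out$flows <- list(D_died = dd[1], D_adapted = dd[2], D_repaired = dd[3],
                    A_died = aa[1], A_repaired = aa[2], R_died = r_died)
  if (out$D < 0 || out$A < 0 || out$R < 0)
    stop("internal error: negative compartment count", call. = FALSE)
  out
}

#' Carrying-capacity division step
#'
#' At the end of each step the adapted and repaired cells divide (each
#' dividing cell adds one daughter to its own compartment) within the limit
#' of the carrying capacity. With `free = Nmax - (D + A + R)` spaces left
#' and `demand = A + R` daughters wanted, both compartments double when
#' `demand <= free`; otherwise exactly `free` daughters are added,
#' apportioned proportionally between `A` and `R` by largest-remainder
#' rounding. Damaged cells are arrested and do not divide, but they occupy
#' space.
#'
#' @inheritParams markov_step
#' @return The post-division `dd_state` (same step index).
#' @export
divide_step <- function(state, params, env = dd_environment()) {
  total <- state$D + state$A + state$R
  if (total > params$Nmax)
    stop("population exceeds the carrying capacity before division",
         call. = FALSE)
  free <- params$Nmax - total
  demand <- state$A + state$R
  if (demand == 0 || free == 0) return(state)
  if (demand <= free) {
    state$A <- 2 * state$A
    state$R <- 2 * state$R
  } else {
    exact_a <- free * state$A / demand
    exact_r <- free * state$R / demand
    add_a <- floor(exact_a)
    add_r <- floor(exact_r)
    short <- free - add_a - add_r   # 0 or 1 with two compartments
    if (short > 0) {
      if (exact_a - add_a >= exact_r - add_r) add_a <- add_a + short
      else add_r <- add_r + short
    }
    state$A <- state$A + add_a
    state$R <- state$R + add_r
  }
  state
}

#' Run the discrete-time stochastic population model
#'
#' Simulates the damaged/adapted/repaired compartments from the initial
#' state of `N0` damaged cells, alternating one Markov transition
#' ([markov_step()]) and one division step ([divide_step()]) per discrete
#' step. The first transition after damage uses step index `n = 1` (so at
#' baseline the repair probability peaks at the very first step). The run
#' stops at the first step with `R >= Nmax` — the saturation time `Ts` — or
#' at `max_steps`, in which case the result is flagged as non-saturated.
#'
#' The run is fully reproducible from `seed`; the caller's RNG state is
#' saved and restored.
#'
#' @param params a [dd_params()] object.
#' @param seed integer seed for the run.
#' @param max_steps maximum number of steps to simulate.
#' @param env a (realised) [dd_environment()].
#' @param keep_trajectory record the per-step compartment counts.
#' @return An object of class `dd_stoch_run`: list with `Ts` (integer step
#'   or `NA`), `saturated`, `seed`, `final`, and (if kept) `trajectory`, a
#'   data.frame with columns `step`, `D`, `A`, `R`, `dead_cum`.
#' @examples
#' run <- run_stochastic(dd_params(), seed = 1)
#' run$Ts
#' @export
run_stochastic <- function(params, seed, max_steps = 500,
                           env = dd_environment(), keep_trajectory = TRUE) {
  stopifnot(inherits(params, "dd_params"), max_steps >= 1)
  if (is_gated(env) && is.null(env$stop_time))
    stop("fluctuating environment has no realised stop time", call. = FALSE)
  check_step_probabilities(params)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)

  state <- population_state(D = params$N0)
  traj <- if (keep_trajectory) {
    out <- matrix(NA_real_, nrow = max_steps + 1L, ncol = 5L,
                  dimnames = list(NULL, c("step", "D", "A", "R",
                                          "dead_cum")))
    out[1L, ] <- c(0, params$N0, 0, 0, 0)
    out
  }
  Ts <- NA_integer_
  for (n in seq_len(max_steps)) {
    state <- markov_step(state, params, env)
    state <- divide_step(state, params, env)
    if (keep_trajectory)
      traj[n + 1L, ] <- c(state$step, state$D, state$A, state$R,
                          state$dead_cum)
    if (state$R >= params$Nmax) {
      Ts <- state$step
      break
    }
  }
  structure(list(Ts = Ts, saturated = !is.na(Ts), seed = seed,
                 final = state,
                 trajectory = if (keep_trajectory)
                   as.data.frame(traj[!is.na(traj[, 1]), , drop = FALSE]),
                 params = params, env = env),
            class = "dd_stoch_run")
}

#' @export
print.dd_stoch_run <- function(x, ...) {
  cat("Stochastic run (dd_stoch_run), seed", x$seed, "\n")
  if (x$saturated)
    cat(sprintf("  saturation time Ts = %d steps\n", x$Ts))
  else
    cat("  not saturated within the step budget\n")
  print(x$final)
  invisible(x)
}

#' @export
plot.dd_stoch_run <- function(x, ...) {
  if (is.null(x$trajectory))
    stop("run was simulated with keep_trajectory = FALSE", call. = FALSE)
  tr <- x$trajectory
  graphics::matplot(tr$step, tr[, c("D", "A", "R")], type = "s", lty = 1,
                    col = c("firebrick", "steelblue", "darkorange"),
                    xlab = "step", ylab = "cells", ...)
  graphics::legend("right", legend = c("D", "A", "R"), lty = 1,
                   col = c("firebrick", "steelblue", "darkorange"),
                   bty = "n")
  invisible(x)
}

#' Mean saturation time over replicate stochastic runs
#'
#' Averages `Ts` over `n_rep` independent runs; replicate `r` uses seed
#' `base_seed + r`. Non-saturating runs are excluded from the average and
#' counted separately; if every run fails to saturate this is an error.
#'
#' @param params a [dd_params()] object.
#' @param n_rep number of replicate runs.
#' @param base_seed base seed; replicate `r` uses `base_seed + r`.
#' @param max_steps per-run step budget.
#' @param env a (realised) [dd_environment()].
#' @return An object of class `dd_ts_summary`: list with `mean`, `se`
#'   (standard error of the mean), `sd`, `n` (saturating runs),
#'   `n_excluded`.
#' @examples
#' mean_saturation_time(dd_params(), n_rep = 20, base_seed = 42)$mean
#' @export
mean_saturation_time <- function(params, n_rep, base_seed = 1,
                                 max_steps = 500, env = dd_environment()) {
  stopifnot(n_rep >= 1)
  ts <- vapply(seq_len(n_rep), function(r) {
    run_stochastic(params, seed = base_seed + r, max_steps = max_steps,
                   env = env, keep_trajectory = FALSE)$Ts
  }, integer(1))
  ok <- !is.na(ts)
  if (!any(ok))
    stop("no replicate saturated within 'max_steps'", call. = FALSE)
  m <- mean(ts[ok])
  s <- stats::sd(ts[ok])
  structure(list(mean = m, se = if (sum(ok) > 1) s / sqrt(sum(ok)) else NA,
                 sd = s, n = sum(ok), n_excluded = sum(!ok)),
            class = "dd_ts_summary")
}

#' @export
print.dd_ts_summary <- function(x, ...) {
  cat(sprintf("mean Ts = %.4f steps (se %.4f, n = %d", x$mean, x$se, x$n))
  if (x$n_excluded > 0)
    cat(sprintf(", %d non-saturating run(s) excluded", x$n_excluded))
  cat(")\n")
  invisible(x)
}
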