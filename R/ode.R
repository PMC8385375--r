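#' Right-hand side of the continuous compartment models
#'
#' Time derivative of the three-compartment system (damaged `D`, adapted
#' `A`, repaired `R`) or, with a four-element state, of its lineage-resolved
#' refinement in which the repaired pool is split into `Rd` (descendants of
#' directly repaired cells) and `Ra` (descendants of cells that adapted and
#' later repaired), `R = Rd + Ra`:
#'
#' \deqn{D' = -(\gamma_1 + \beta(t) + \alpha_{env}(t))\, D}
#' \deqn{A' = \beta(t) D - (\gamma_{ad} + \delta) A + A (1 - N/N_{max})}
#' \deqn{R_d' = \alpha_{env}(t) D - \gamma_r R_d + R_d (1 - N/N_{max})}
#' \deqn{R_a' = \delta A - \gamma_r R_a + R_a (1 - N/N_{max})}
#'
#' with total population `N = D + A + Rd + Ra` appearing only through the
#' logistic crowding factor, which multiplies only the growth terms (damaged
#' cells are arrested and have none, but they do occupy space in `N`). The
#' crowding factor is not clipped: it may transiently be negative if `N`
#' overshoots `Nmax`. Negative state components (solver undershoot) are
#' treated as 0.
#'
#' @param t time (steps).
#' @param state numeric vector of length 3 (`D`, `A`, `R`) or 4
#'   (`D`, `A`, `Rd`, `Ra`).
#' @param params a [dd_params()] object.
#' @param env a (realised) [dd_environment()]; the stable environment by
#'   default.
#' @return Numeric vector: the derivative of `state`.
#' @seealso [run_ode()]
#' @export
ode_rhs <- function(t, state, params, env = dd_environment()) {
  y <- pmax(state, 0)
  a <- alpha_env(t, env, params)
  b <- beta_at(t, params)
  crowd <- 1 - sum(y) / params$Nmax
  if (length(y) == 3L) {
    c(-(params$gamma1 + b + a) * y[1],
      b * y[1] - (params$gamma_ad + params$delta) * y[2] + y[2] * crowd,
      a * y[1] + params$delta * y[2] - params$gamma_r * y[3] + y[3] * crowd)
  } else if (length(y) == 4L) {
    c(-(params$gamma1 + b + a) * y[1],
      b * y[1] - (params$gamma_ad + params$delta) * y[2] + y[2] * crowd,
      a * y[1] - params$gamma_r * y[3] + y[3] * crowd,
      params$delta * y[2] - params$gamma_r * y[4] + y[4] * crowd)
  } else {
    stop("'state' must have length 3 or 4", call. = FALSE)
  }
}

# fast closure for deSolve; inlines the curves and counts negative clips.
# `shift` = 0 for the original repair clock, tau for a restarted window;
# `amp` rescales alpha_m (fading environments); `gate_off` suppresses repair
# entirely (the pre-stop phase).
make_rhs <- function(params, clip_counter, shift = 0, amp = 1,
                     gate_off = FALSE) {
  g1 <- params$gamma1; gad <- params$gamma_ad; gr <- params$gamma_r
  dl <- params$delta; am <- amp * params$alpha_m
  s2 <- params$sigma^2; ma <- params$mu_a
  bm <- params$beta_m; p <- params$p; mb <- params$mu_b
  Nmax <- params$Nmax
  function(t, y, parms) {
    if (any(y < 0)) {
      clip_counter$n <- clip_counter$n + 1L
      y <- pmax(y, 0)
    }
    a <- if (gate_off) 0 else am * exp(-((t - shift) - ma)^2 / s2)
    b <- bm / (1 + exp(-p * (t - mb)))
    crowd <- 1 - sum(y) / Nmax
    if (length(y) == 3L) {
      list(c(-(g1 + b + a) * y[1],
             b * y[1] - (gad + dl) * y[2] + y[2] * crowd,
             a * y[1] + dl * y[2] - gr * y[3] + y[3] * crowd))
    } else {
      list(c(-(g1 + b + a) * y[1],
             b * y[1] - (gad + dl) * y[2] + y[2] * crowd,
             a * y[1] - gr * y[3] + y[3] * crowd,
             dl * y[2] - gr * y[4] + y[4] * crowd))
    }
  }
}

#' Integrate the continuous population model
#'
#' Integrates the three-compartment ODE model (or, with `lineage = TRUE`,
#' the four-compartment lineage-resolved extension) from the initial state
#' of `N0` damaged cells, using `deSolve`'s `lsodar` (adaptive,
#' stiff-switching, with built-in root finding). The saturation time `Ts` is
#' the first time at which the healthy compartment fills the environment to
#' within one cell, `Nmax - R(t) < 1`; it is located by the solver's root
#' finder on the event function `R(t) - (Nmax - 1)` and the integration
#' stops there unless `stop_at_saturation = FALSE`.
#'
#' In a fluctuating environment with stop time `tau` the integration is
#' split at `tau` (where the effective repair probability is discontinuous):
#' repair is off on `[0, tau]` and follows the environment's resume mode
#' afterwards.
#'
#' @param params a [dd_params()] object.
#' @param env a [dd_environment()]; fluctuating kinds must carry a realised
#'   `stop_time`.
#' @param t_max integration horizon (steps); a run that has not saturated by
#'   `t_max` is returned with `Ts = NA` and `saturated = FALSE`, not an
#'   error.
#' @param lineage integrate the four-compartment model (`D`, `A`, `Rd`,
#'   `Ra`) instead of the three-compartment one.
#' @param times optional output time grid for the stored trajectory; by
#'   default only the endpoints are stored (the saturation time is located
#'   by root finding regardless of the output grid).
#' @param rtol,atol relative and absolute solver tolerances; the absolute
#'   tolerance is scaled to the carrying capacity.
#' @param stop_at_saturation stop integrating at `Ts` (default; root-finder
#'   accuracy) or continue to `t_max`, in which case `Ts` is reported only
#'   to the resolution of the output grid.
#' @return An object of class `dd_ode_run`: list with `times`, `state` (one
#'   row per stored time), `Ts`, `saturated`, `final_state`, `lineage`,
#'   `diagnostics` (tolerances and the number of negative-undershoot clips),
#'   `params`, `env`.
#' @examples
#' run <- run_ode(dd_params())
#' run$Ts
#' @export
run_ode <- function(params, env = dd_environment(), t_max = 500,
                    lineage = FALSE, times = NULL,
                    rtol = 1e-8, atol = 1e-8 * params$Nmax,
                    stop_at_saturation = TRUE) {
  stopifnot(inherits(params, "dd_params"), inherits(env, "dd_env"))
  if (t_max <= 0) stop("'t_max' must be positive", call. = FALSE)
  if (is_gated(env) && is.null(env$stop_time))
    stop("fluctuating environment has no realised stop time; set ",
         "'stop_time' or average over build_ensemble()", call. = FALSE)

  y0 <- if (lineage) c(D = params$N0, A = 0, Rd = 0, Ra = 0) else
    c(D = params$N0, A = 0, R = 0)
  healthy <- function(y) if (lineage) y[3] + y[4] else y[3]
  rootfun <- function(t, y, parms) healthy(y) - (params$Nmax - 1)
  clip <- new.env(parent = emptyenv()); clip$n <- 0L

  tau <- if (is_gated(env)) min(env$stop_time, t_max) else 0
  amp <- if (env$kind == "uniform_stop_fading")
    exp(-env$fade * env$stop_time) else 1
  shift <- if (is_gated(env) && env$resume == "restart") env$stop_time else 0

  seg_times <- function(lo, hi) {
    tt <- c(lo, times[times > lo & times < hi], hi)
    unique(tt)
  }
  run_segment <- function(y, lo, hi, rhs) {
    if (stop_at_saturation)
      deSolve::ode(y = y, times = seg_times(lo, hi), func = rhs,
                   parms = NULL, method = "lsodar", rootfun = rootfun,
                   rtol = rtol, atol = atol)
    else
      deSolve::ode(y = y, times = seg_times(lo, hi), func = rhs,
                   parms = NULL, method = "lsoda",
                   rtol = rtol, atol = atol)
  }

  out_all <- NULL
  roots <- numeric(0)
  append_out <- function(out) {
    troot <- attr(out, "troot")
    if (!is.null(troot)) roots <<- c(roots, troot)
    out_all <<- if (is.null(out_all)) unclass(out) else
      rbind(out_all, unclass(out)[-1, , drop = FALSE])
  }

  if (tau > 0) {
    out1 <- run_segment(y0, 0, tau, make_rhs(params, clip, gate_off = TRUE))
    append_out(out1)
    y0 <- out1[nrow(out1), -1]
    t_reached <- out1[nrow(out1), 1]
  } else {
    t_reached <- 0
  }
  stopped <- stop_at_saturation && length(roots) > 0
  if (!stopped && t_reached < t_max) {
    out2 <- run_segment(y0, t_reached, t_max,
                        make_rhs(params, clip, shift = shift, amp = amp))
    append_out(out2)
  }

  final_state <- out_all[nrow(out_all), -1]
  if (!is.null(times)) {
    keep <- out_all[, 1] %in% times
    if (any(keep)) out_all <- out_all[keep, , drop = FALSE]
  }
  state <- out_all[, -1, drop = FALSE]
  Ts <- if (length(roots) > 0) {
    min(roots)
  } else if (!stop_at_saturation) {
    # located only to the resolution of the output grid in this mode
    healthy_traj <- if (lineage) state[, 3] + state[, 4] else state[, 3]
    hit <- which(healthy_traj >= params$Nmax - 1)
    if (length(hit) > 0) out_all[hit[1], 1] else NA_real_
  } else {
    NA_real_
  }
  structure(list(times = out_all[, 1], state = state,
                 Ts = Ts, saturated = is.finite(Ts),
                 final_state = final_state,
                 lineage = lineage,
                 diagnostics = list(rtol = rtol, atol = atol,
                                    n_clipped = clip$n),
                 params = params, env = env),
            class = "dd_ode_run")
}

#' Saturation time of a run
#'
#' The first time at which the healthy (repaired) compartment fills the
#' carrying capacity: `Nmax - R(t) < 1` for the continuous model,
#' `R >= Nmax` for the stochastic one. `NA` if the run did not saturate.
#'
#' @param run a [run_ode()] or [run_stochastic()] result.
#' @return A single number (steps), or `NA`.
#' @export
saturation_time <- function(run) run$Ts

#' Fraction of survivors descended from adapted cells
#'
#' For a saturated four-compartment run, the share of the healthy population
#' at saturation that went through adaptation before repairing:
#' `Ra(Ts) / (Rd(Ts) + Ra(Ts))`. A proxy for the genetic diversity
#' contributed by adaptation (adapted divisions are mutagenic).
#'
#' @param run a [run_ode()] result with `lineage = TRUE` that saturated.
#' @return A fraction in `[0, 1]`.
#' @export
structure_fraction <- function(run) {
  if (!inherits(run, "dd_ode_run") || !run$lineage)
    stop("'run' must be a four-compartment (lineage = TRUE) ODE run",
         call. = FALSE)
  if (!run$saturated)
    stop("run did not saturate; the structure fraction is undefined",
         call. = FALSE)
  y <- run$final_state
  tot <- y[["Rd"]] + y[["Ra"]]
  if (tot <= 0)
    stop("no healthy cells at saturation; fraction undefined", call. = FALSE)
  unname(y[["Ra"]] / tot)
}

#' @export
print.dd_ode_run <- function(x, ...) {
  cat(sprintf("Continuous %d-compartment run (dd_ode_run)\n",
              ncol(x$state)))
  if (x$saturated)
    cat(sprintf("  saturation time Ts = %.4f steps\n", x$Ts))
  else
    cat(sprintf("  not saturated by t = %.4g\n", max(x$times)))
  fs <- x$final_state
  cat("  final state: ",
      paste(sprintf("%s = %.4g", names(fs), fs), collapse = ", "), "\n")
  if (x$lineage && x$saturated)
    cat(sprintf("  adapted-ancestry fraction: %.4f\n",
                structure_fraction(x)))
  invisible(x)
}

#' @export
plot.dd_ode_run <- function(x, ...) {
  if (length(x$times) < 3L)
    stop("no stored trajectory; rerun run_ode() with a 'times' grid",
         call. = FALSE)
  cols <- c("firebrick", "steelblue", "darkorange", "darkgreen")
  graphics::matplot(x$times, x$state, type = "l", lty = 1,
                    col = cols[seq_len(ncol(x$state))],
                    xlab = "time (steps)", ylab = "cells", ...)
  graphics::legend("right", legend = colnames(x$state), lty = 1,
                   col = cols[seq_len(ncol(x$state))], bty = "n")
  if (x$saturated) graphics::abline(v = x$Ts, lty = 3)
  invisible(x)
}
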