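#' Golden-section minimisation on an interval
#'
#' Plain golden-section search for a unimodal scalar function, used to
#' refine sweep minima between grid neighbours.
#'
#' @param f function of one numeric argument.
#' @param lower,upper bracketing interval.
#' @param tol absolute tolerance on the argmin location.
#' @return List with `minimum` (location) and `objective` (value).
#' @keywords internal
golden_section <- function(f, lower, upper, tol = 1e-3) {
  invphi <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  c_ <- b - invphi * (b - a)
  d_ <- a + invphi * (b - a)
  fc <- f(c_); fd <- f(d_)
  while (b - a > tol) {
    if (fc <= fd) {
      b <- d_; d_ <- c_; fd <- fc
      c_ <- b - invphi * (b - a); fc <- f(c_)
    } else {
      a <- c_; c_ <- d_; fc <- fd
      d_ <- a + invphi * (b - a); fd <- f(d_)
    }
  }
  x <- (a + b) / 2
  list(minimum = x, objective = f(x))
}

# saturation-time evaluator shared by the sweep drivers: returns a
# function(overrides) -> c(Ts, se), dispatching on model and environment
ts_evaluator <- function(params, model, env, t_max, n_rep, base_seed) {
  if (inherits(env, "dd_ensemble") ||
      (inherits(env, "dd_env") && is_gated(env) && is.null(env$stop_time))) {
    ensemble <- if (inherits(env, "dd_ensemble")) env else
      build_ensemble(env)
    if (model != "ode")
      stop("ensemble averaging is implemented for the ODE model",
           call. = FALSE)
    function(...) {
      p <- modify_params(params, ...)
      v <- tryCatch(
        expected_over_environment(p, ensemble, t_max = t_max)$value,
        error = function(e) NA_real_)
      c(v, NA_real_)
    }
  } else if (model == "ode") {
    function(...) {
      p <- modify_params(params, ...)
      c(run_ode(p, env = env, t_max = t_max)$Ts, NA_real_)
    }
  } else {
    function(...) {
      p <- modify_params(params, ...)
      s <- tryCatch(
        mean_saturation_time(p, n_rep = n_rep, base_seed = base_seed,
                             max_steps = t_max, env = env),
        error = function(e) NULL)
      if (is.null(s)) c(NA_real_, NA_real_) else c(s$mean, s$se)
    }
  }
}

sweep_1d <- function(params, grid, vary, model, env, refine, n_rep,
                     base_seed, t_max) {
  model <- match.arg(model, c("ode", "stochastic"))
  stopifnot(is.numeric(grid), length(grid) >= 1, !is.unsorted(sort(grid)))
  grid <- sort(grid)
  ev <- ts_evaluator(params, model, env, t_max, n_rep, base_seed)
  res <- t(vapply(grid, function(v) {
    do.call(ev, stats::setNames(list(v), vary))
  }, numeric(2)))
  data <- data.frame(value = grid, Ts = res[, 1], se = res[, 2])
  names(data)[1] <- vary

  sat <- which(is.finite(data$Ts))
  argmin <- Ts_min <- argmin_refined <- Ts_refined <- NA_real_
  if (length(sat) > 0) {
    i <- sat[which.min(data$Ts[sat])]
    argmin <- grid[i]; Ts_min <- data$Ts[i]
    argmin_refined <- argmin; Ts_refined <- Ts_min
    if (refine && model == "ode" && length(grid) > 1) {
      lo <- grid[max(1L, i - 1L)]
      hi <- grid[min(length(grid), i + 1L)]
      if (hi > lo) {
        opt <- golden_section(function(v) {
          do.call(ev, stats::setNames(list(v), vary))[1]
        }, lo, hi, tol = 1e-3)
        argmin_refined <- opt$minimum; Ts_refined <- opt$objective
      }
    }
  }
  structure(list(data = data, param = vary, model = model,
                 argmin = argmin, Ts_min = Ts_min,
                 argmin_refined = argmin_refined, Ts_refined = Ts_refined,
                 n_nonsaturating = sum(!is.finite(data$Ts)),
                 env = env, params = params),
            class = "dd_sweep")
}

#' Saturation time as a function of the adaptation timing
#'
#' Computes the saturation time `Ts` for each value of the adaptation
#' half-maximum time `mu_b` on a grid, locates the grid argmin (the optimal
#' adaptation timing) and, for the ODE model, refines it by golden-section
#' search between the two grid neighbours of the discrete minimum (to an
#' absolute resolution of 1e-3). Non-saturating grid points are recorded
#' with `Ts = NA` and excluded from the argmin.
#'
#' @param params a [dd_params()] object; its `p` stays fixed during the
#'   sweep.
#' @param grid values of `mu_b` to test (steps).
#' @param model `"ode"` (deterministic, default) or `"stochastic"` (mean
#'   over replicates).
#' @param env a [dd_environment()] or [build_ensemble()] result; an
#'   unrealised fluctuating environment is expanded into its default
#'   quadrature ensemble and `Ts` becomes the environment expectation.
#' @param refine refine the argmin by golden-section search (ODE only).
#' @param n_rep,base_seed replicates and base seed for the stochastic model.
#' @param t_max integration / step horizon.
#' @return An object of class `dd_sweep`: list with `data` (one row per
#'   grid point), `argmin`, `argmin_refined`, `Ts_min`, `Ts_refined`.
#' @examples
#' sw <- sweep_mu_b(dd_params(), grid = seq(2, 5, by = 0.5))
#' sw$argmin_refined
#' @export
sweep_mu_b <- function(params, grid = seq(0, 10, by = 0.05),
                       model = c("ode", "stochastic"),
                       env = dd_environment(), refine = TRUE,
                       n_rep = 10000, base_seed = 1, t_max = 500) {
  sweep_1d(params, grid, "mu_b", match.arg(model), env, refine, n_rep,
           base_seed, t_max)
}

#' Saturation time as a function of the adaptation heterogeneity
#'
#' As [sweep_mu_b()], but sweeping the logistic slope parameter `p`, which
#' controls the heterogeneity of adaptation timing: small `p` spreads
#' adaptation over many steps (heterogeneous timing), large `p` makes every
#' cell adapt in a narrow time window. `mu_b` stays fixed.
#'
#' @inheritParams sweep_mu_b
#' @param grid values of `p` to test.
#' @return A `dd_sweep` object; see [sweep_mu_b()].
#' @export
sweep_p <- function(params, grid = seq(0.1, 10, by = 0.1),
                    model = c("ode", "stochastic"),
                    env = dd_environment(), refine = TRUE,
                    n_rep = 10000, base_seed = 1, t_max = 500) {
  sweep_1d(params, grid, "p", match.arg(model), env, refine, n_rep,
           base_seed, t_max)
}

#' @export
print.dd_sweep <- function(x, ...) {
  cat(sprintf("Sweep of '%s' over %d grid points (%s model)\n",
              x$param, nrow(x$data), x$model))
  if (is.finite(x$argmin)) {
    cat(sprintf("  grid argmin:    %s = %g (Ts = %.4f)\n", x$param,
                x$argmin, x$Ts_min))
    cat(sprintf("  refined argmin: %s = %.4f (Ts = %.4f)\n", x$param,
                x$argmin_refined, x$Ts_refined))
  } else {
    cat("  no saturating grid point\n")
  }
  if (x$n_nonsaturating > 0)
    cat(sprintf("  %d non-saturating grid point(s)\n", x$n_nonsaturating))
  invisible(x)
}

#' @export
plot.dd_sweep <- function(x, ...) {
  plot(x$data[[x$param]], x$data$Ts, type = "l", xlab = x$param,
       ylab = "saturation time Ts (steps)", ...)
  if (is.finite(x$argmin_refined))
    graphics::abline(v = x$argmin_refined, lty = 3)
  invisible(x)
}

#' Saturation time over the (mu_b, p) plane
#'
#' Full grid of `Ts` over adaptation timing and heterogeneity. For each
#' `mu_b` the optimal `p` is extracted and classified as a boundary optimum
#' (the largest tested `p` wins — sharp adaptation is best) or an interior
#' optimum (an intermediate heterogeneity wins). Non-saturating cells are
#' `NA`.
#'
#' @inheritParams sweep_mu_b
#' @param mu_b_grid,p_grid grid values for the two axes.
#' @return An object of class `dd_sweep_grid`: list with `Ts` (matrix,
#'   rows = `mu_b`, columns = `p`), the two grids, and `per_mu_b`, a
#'   data.frame with columns `mu_b`, `p_opt`, `interior`.
#' @export
sweep_grid <- function(params, mu_b_grid, p_grid,
                       model = c("ode", "stochastic"),
                       env = dd_environment(), n_rep = 10000,
                       base_seed = 1, t_max = 500) {
  model <- match.arg(model)
  stopifnot(length(mu_b_grid) >= 1, length(p_grid) >= 1)
  mu_b_grid <- sort(mu_b_grid); p_grid <- sort(p_grid)
  ev <- ts_evaluator(params, model, env, t_max, n_rep, base_seed)
  Ts <- matrix(NA_real_, length(mu_b_grid), length(p_grid),
               dimnames = list(mu_b = format(mu_b_grid),
                               p = format(p_grid)))
  for (i in seq_along(mu_b_grid))
    for (j in seq_along(p_grid))
      Ts[i, j] <- ev(mu_b = mu_b_grid[i], p = p_grid[j])[1]
  per <- data.frame(mu_b = mu_b_grid, p_opt = NA_real_, interior = NA)
  for (i in seq_along(mu_b_grid)) {
    ok <- which(is.finite(Ts[i, ]))
    if (length(ok) == 0) next
    j <- ok[which.min(Ts[i, ok])]
    per$p_opt[i] <- p_grid[j]
    per$interior[i] <- j > 1 && j < length(p_grid)
  }
  structure(list(Ts = Ts, mu_b_grid = mu_b_grid, p_grid = p_grid,
                 per_mu_b = per, model = model, params = params,
                 env = env),
            class = "dd_sweep_grid")
}

#' @export
print.dd_sweep_grid <- function(x, ...) {
  cat(sprintf("Ts grid: %d mu_b x %d p values (%s model)\n",
              length(x$mu_b_grid), length(x$p_grid), x$model))
  n_int <- sum(x$per_mu_b$interior, na.rm = TRUE)
  cat(sprintf("  interior p-optimum at %d of %d mu_b values\n",
              n_int, nrow(x$per_mu_b)))
  invisible(x)
}

#' @export
plot.dd_sweep_grid <- function(x, ...) {
  z <- x$Ts
  graphics::image(x$mu_b_grid, x$p_grid, z, xlab = "mu_b", ylab = "p",
                  col = grDevices::hcl.colors(64, "viridis", rev = TRUE),
                  ...)
  invisible(x)
}

#' Optimal adaptation timing as a function of the repair timing
#'
#' For each repair-window centre `mu_a` on a grid, sweeps `mu_b` (ODE
#' model, refined argmin) and reports the optimal adaptation timing and
#' the delay `mu_b_opt - mu_a` between repair and adaptation.
#'
#' @inheritParams sweep_mu_b
#' @param mu_a_grid repair-curve centres to test (steps, positive).
#' @param mu_b_grid grid for the inner `mu_b` sweep.
#' @return An object of class `dd_delay`: a data.frame with columns
#'   `mu_a`, `mu_b_opt`, `delay`.
#' @export
optimal_mu_b_vs_mu_a <- function(params, mu_a_grid,
                                 mu_b_grid = seq(0, 10, by = 0.05),
                                 env = dd_environment(), t_max = 500) {
  stopifnot(all(mu_a_grid > 0))
  rows <- lapply(mu_a_grid, function(ma) {
    p <- modify_params(params, mu_a = ma)
    sw <- sweep_mu_b(p, grid = mu_b_grid, model = "ode", env = env,
                     t_max = t_max)
    data.frame(mu_a = ma, mu_b_opt = sw$argmin_refined,
               delay = sw$argmin_refined - ma)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dd_delay", "data.frame")
  out
}

#' Adapted-ancestry structure of the surviving population
#'
#' For each adaptation-heterogeneity value `p`, runs the four-compartment
#' model to saturation and reports the fraction of healthy cells descended
#' from adapted cells, `Ra(Ts) / (Rd(Ts) + Ra(Ts))` — in a fluctuating
#' environment, the expectation of the per-environment fraction over the
#' stop-time distribution.
#'
#' @inheritParams sweep_mu_b
#' @param p_grid values of `p` to test.
#' @return An object of class `dd_structure`: a data.frame with columns
#'   `p` and `fraction`.
#' @examples
#' population_structure(dd_params(), p_grid = c(0.5, 1, 3))
#' @export
population_structure <- function(params, env = dd_environment(),
                                 p_grid = seq(0.1, 10, by = 0.1),
                                 t_max = 500) {
  ens <- if (inherits(env, "dd_ensemble")) env else
    if (is_gated(env) && is.null(env$stop_time)) build_ensemble(env) else
      NULL
  frac <- vapply(p_grid, function(pp) {
    p <- modify_params(params, p = pp)
    if (is.null(ens)) {
      structure_fraction(run_ode(p, env = env, lineage = TRUE,
                                 t_max = t_max))
    } else {
      expected_over_environment(p, ens, functional = structure_fraction,
                                lineage = TRUE, t_max = t_max)$value
    }
  }, numeric(1))
  out <- data.frame(p = p_grid, fraction = frac)
  class(out) <- c("dd_structure", "data.frame")
  out
}
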