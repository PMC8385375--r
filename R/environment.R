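#' Damage environments: stable or with a random stop time
#'
#' In the stable environment the damage occurs once at time 0 and the repair
#' window [alpha_at()] applies unchanged. In a fluctuating environment the
#' damage source remains active for a random duration `tau` (the stop time):
#' no repair is possible while the source is active, so the effective repair
#' probability is zero for `t < tau`. Adaptation is never gated; the
#' checkpoint clock runs from the initial damage at time 0.
#'
#' After the stop time the repair probability follows one of two readings of
#' how repair resumes, selected by `resume`:
#' \describe{
#'   \item{`"continue"` (default)}{the repair curve keeps its original clock
#'     and is simply un-gated: `alpha_env(t) = alpha_at(t)` for `t >= tau`.
#'     Repair opportunities that fell inside the damage phase are lost.}
#'   \item{`"restart"`}{the repair window restarts at the stop time:
#'     `alpha_env(t) = alpha_m * exp(-((t - tau) - mu_a)^2 / sigma^2)` for
#'     `t >= tau`, i.e. the full window re-opens once the source stops.}
#' }
#' For the `"uniform_stop_fading"` kind the window always restarts and its
#' height fades exponentially with the stop time,
#' `alpha_m * exp(-fade * tau)`.
#'
#' The stop-time laws are: `"gaussian_stop"` — Normal(`mean`, `variance`)
#' truncated at 0; `"exponential_stop"` — Exponential(`rate`);
#' `"uniform_stop_fading"` — Uniform(`lower`, `upper`).
#'
#' @param kind one of `"stable"`, `"gaussian_stop"`, `"exponential_stop"`,
#'   `"uniform_stop_fading"`.
#' @param stop_time a realised stop time `tau >= 0`, or `NULL` for an
#'   unrealised environment (a law to be expanded by [build_ensemble()]).
#' @param mean,variance parameters of the Gaussian stop-time law (steps,
#'   steps^2).
#' @param rate rate of the exponential stop-time law (1/steps).
#' @param lower,upper bounds of the uniform stop-time law (steps).
#' @param fade exponential fade rate of the repair amplitude with the stop
#'   time (`"uniform_stop_fading"` only).
#' @param resume `"continue"` or `"restart"`; see Details.
#' @return An object of class `dd_env`.
#' @seealso [alpha_env()], [build_ensemble()], [expected_over_environment()]
#' @examples
#' stable <- dd_environment()
#' fluct <- dd_environment("gaussian_stop", stop_time = 1.7)
#' alpha_env(c(1, 2, 3), fluct, dd_params())
#' @export
dd_environment <- function(kind = c("stable", "gaussian_stop",
                                    "exponential_stop",
                                    "uniform_stop_fading"),
                           stop_time = NULL,
                           mean = 1.7, variance = 2.25,
                           rate = 1 / 1.7,
                           lower = 0, upper = 3.4,
                           fade = 0.3,
                           resume = c("continue", "restart")) {
  kind <- match.arg(kind)
  resume <- match.arg(resume)
  problems <- character(0)
  if (kind == "gaussian_stop" && variance <= 0)
    problems <- c(problems, sprintf("'variance' must be > 0 (got %g)",
                                    variance))
  if (kind == "exponential_stop" && rate <= 0)
    problems <- c(problems, sprintf("'rate' must be > 0 (got %g)", rate))
  if (kind == "uniform_stop_fading") {
    if (lower > upper)
      problems <- c(problems,
                    sprintf("'lower' must not exceed 'upper' (got %g > %g)",
                            lower, upper))
    if (lower < 0)
      problems <- c(problems, sprintf("'lower' must be >= 0 (got %g)", lower))
    if (fade < 0)
      problems <- c(problems, sprintf("'fade' must be >= 0 (got %g)", fade))
    resume <- "restart"  # the fading window is defined from the stop time
  }
  if (!is.null(stop_time)) {
    if (!is.numeric(stop_time) || length(stop_time) != 1L ||
        !is.finite(stop_time) || stop_time < 0)
      problems <- c(problems, "'stop_time' must be a single number >= 0")
  }
  if (length(problems) > 0L)
    stop("invalid environment:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(list(kind = kind, stop_time = stop_time, mean = mean,
                 variance = variance, rate = rate, lower = lower,
                 upper = upper, fade = fade, resume = resume),
            class = "dd_env")
}

# a copy of `env` with the stop time set to `tau`
realize_env <- function(env, tau) {
  env$stop_time <- tau
  env
}

is_gated <- function(env) env$kind != "stable"

#' Environment-modulated repair probability
#'
#' The effective repair probability at time `t` under an environment: equal
#' to [alpha_at()] in the stable environment; zero while the damage source is
#' active (`t < stop_time`); and afterwards either the original curve
#' (`resume = "continue"`) or a restarted, possibly faded, window
#' (`resume = "restart"`). See [dd_environment()].
#'
#' @param t time since the initial damage, in steps; vectorised.
#' @param env a realised [dd_environment()] (with `stop_time` set, unless
#'   stable).
#' @param params a [dd_params()] object.
#' @return Numeric vector of probabilities.
#' @export
alpha_env <- function(t, env, params) {
  if (!is_gated(env)) return(alpha_at(t, params))
  tau <- env$stop_time
  if (is.null(tau))
    stop("environment has no realised stop time; ",
         "set 'stop_time' or use build_ensemble()", call. = FALSE)
  amp <- if (env$kind == "uniform_stop_fading") exp(-env$fade * tau) else 1
  post <- if (env$resume == "restart") {
    amp * params$alpha_m * exp(-((t - tau) - params$mu_a)^2 / params$sigma^2)
  } else {
    alpha_at(t, params)
  }
  ifelse(t < tau, 0, post)
}

#' @export
print.dd_env <- function(x, ...) {
  if (x$kind == "stable") {
    cat("Damage environment: stable (repair curve ungated)\n")
    return(invisible(x))
  }
  law <- switch(x$kind,
    gaussian_stop = sprintf("Normal(mean %g, variance %g) truncated at 0",
                            x$mean, x$variance),
    exponential_stop = sprintf("Exponential(rate %g)", x$rate),
    uniform_stop_fading = sprintf("Uniform(%g, %g), amplitude fade %g",
                                  x$lower, x$upper, x$fade))
  cat(sprintf("Damage environment: %s\n  stop-time law: %s\n", x$kind, law))
  cat(sprintf("  repair resumes: %s\n", x$resume))
  if (!is.null(x$stop_time))
    cat(sprintf("  realised stop time: %g steps\n", x$stop_time))
  invisible(x)
}

# quantile, density and sampler of the (0-truncated) stop-time law
law_functions <- function(env) {
  switch(env$kind,
    gaussian_stop = {
      sd <- sqrt(env$variance)
      p0 <- stats::pnorm(0, env$mean, sd)
      list(
        quantile = function(q) max(0, stats::qnorm(q, env$mean, sd)),
        density = function(x) stats::dnorm(x, env$mean, sd) / (1 - p0),
        sample = function(n) stats::qnorm(stats::runif(n, p0, 1),
                                          env$mean, sd))
    },
    exponential_stop = list(
      quantile = function(q) stats::qexp(q, env$rate),
      density = function(x) stats::dexp(x, env$rate),
      sample = function(n) stats::rexp(n, env$rate)),
    uniform_stop_fading = list(
      quantile = function(q) stats::qunif(q, env$lower, env$upper),
      density = function(x) stats::dunif(x, env$lower, env$upper),
      sample = function(n) stats::runif(n, env$lower, env$upper)),
    stop("the stable environment has no stop-time law", call. = FALSE))
}

#' Expand a stop-time law into a weighted ensemble of environments
#'
#' Discretises the stop-time distribution of a fluctuating environment into
#' nodes `(tau_i, w_i)` with `sum(w_i) = 1`, for computing expectations over
#' the random environment. The default is deterministic trapezoid quadrature
#' on a uniform `tau` grid spanning `[0, q(0.9999)]` of the law, with weights
#' proportional to the (0-truncated, renormalised) density; `"monte-carlo"`
#' instead draws `n_nodes` i.i.d. stop times with equal weights.
#'
#' An environment whose `stop_time` is already realised (and a stable
#' environment) yield a single node of weight 1.
#'
#' @param env a [dd_environment()] with a stop-time law.
#' @param n_nodes number of nodes (at least 2 for quadrature).
#' @param method `"quadrature"` or `"monte-carlo"`.
#' @param seed integer seed for the Monte-Carlo draws (ignored for
#'   quadrature); the caller's RNG state is left untouched.
#' @return An object of class `dd_ensemble`: a list with `nodes` (a
#'   data.frame with columns `tau`, `weight`) and the template environment.
#' @examples
#' ens <- build_ensemble(dd_environment("gaussian_stop"), n_nodes = 50)
#' sum(ens$nodes$weight)
#' @export
build_ensemble <- function(env, n_nodes = 200,
                           method = c("quadrature", "monte-carlo"),
                           seed = NULL) {
  method <- match.arg(method)
  if (!is_gated(env) || !is.null(env$stop_time)) {
    tau <- if (is_gated(env)) env$stop_time else NA_real_
    return(structure(list(nodes = data.frame(tau = tau, weight = 1),
                          env = env, method = "point-mass"),
                     class = "dd_ensemble"))
  }
  if (n_nodes < 2L) stop("'n_nodes' must be at least 2", call. = FALSE)
  law <- law_functions(env)
  if (method == "quadrature") {
    tau <- seq(0, law$quantile(0.9999), length.out = n_nodes)
    h <- diff(tau)
    trap <- c(h / 2, 0) + c(0, h / 2)
    w <- law$density(tau) * trap
    w <- w / sum(w)
  } else {
    if (!is.null(seed)) {
      old <- get0(".Random.seed", globalenv(), inherits = FALSE)
      on.exit(restore_rng(old), add = TRUE)
      set.seed(seed)
    }
    tau <- law$sample(n_nodes)
    w <- rep(1 / n_nodes, n_nodes)
  }
  structure(list(nodes = data.frame(tau = tau, weight = w), env = env,
                 method = method),
            class = "dd_ensemble")
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.dd_ensemble <- function(x, ...) {
  cat(sprintf("Environment ensemble: %d node(s), method = %s\n",
              nrow(x$nodes), x$method))
  print(x$env)
  invisible(x)
}

#' Expectation of a run functional over the random environment
#'
#' Runs the continuous model once per ensemble node and returns the
#' weighted expectation of a scalar functional of the run — by default the
#' saturation time. Nodes whose functional is undefined (e.g. runs that do
#' not saturate within `t_max`) are excluded and the remaining weights are
#' renormalised; more than 5% excluded weight raises a warning and more than
#' 50% an error.
#'
#' @param params a [dd_params()] object.
#' @param ensemble a [build_ensemble()] result (or an environment, taken as
#'   a single node).
#' @param functional function mapping a [run_ode()] result to a scalar; use
#'   [saturation_time] (default) or [structure_fraction].
#' @param ... further arguments passed to [run_ode()] (e.g. `lineage`,
#'   `t_max`).
#' @return An object of class `dd_expectation`: list with `value` (the
#'   weighted expectation), `nodes` (per-node tau, weight, value),
#'   `excluded_weight`.
#' @examples
#' ens <- build_ensemble(dd_environment("gaussian_stop"), n_nodes = 20)
#' expected_over_environment(dd_params(), ens)$value
#' @export
expected_over_environment <- function(params, ensemble,
                                      functional = saturation_time, ...) {
  if (inherits(ensemble, "dd_env"))
    ensemble <- build_ensemble(ensemble)
  stopifnot(inherits(ensemble, "dd_ensemble"))
  nodes <- ensemble$nodes
  vals <- vapply(seq_len(nrow(nodes)), function(i) {
    env_i <- if (is.na(nodes$tau[i])) ensemble$env else
      realize_env(ensemble$env, nodes$tau[i])
    v <- functional(run_ode(params, env = env_i, ...))
    if (is.null(v) || !is.finite(v)) NA_real_ else v
  }, numeric(1))
  ok <- !is.na(vals)
  excluded <- sum(nodes$weight[!ok])
  if (excluded > 0.5)
    stop(sprintf("%.1f%% of the environment weight yields no defined value",
                 100 * excluded), call. = FALSE)
  if (excluded > 0.05)
    warning(sprintf("excluding %.1f%% of the environment weight",
                    100 * excluded), call. = FALSE)
  value <- sum(nodes$weight[ok] * vals[ok]) / sum(nodes$weight[ok])
  structure(list(value = value,
                 nodes = cbind(nodes, value = vals, ok = ok),
                 excluded_weight = excluded),
            class = "dd_expectation")
}

#' @export
print.dd_expectation <- function(x, ...) {
  cat(sprintf("Environment expectation: %.6g (%d/%d nodes",
              x$value, sum(x$nodes$ok), nrow(x$nodes)))
  if (x$excluded_weight > 0)
    cat(sprintf(", %.2f%% weight excluded", 100 * x$excluded_weight))
  cat(")\n")
  invisible(x)
}

#' Ensemble-averaged compartment trajectories
#'
#' Integrates the (by default four-compartment) continuous model once per
#' ensemble node and returns the weight-averaged compartment sizes on a
#' common time grid — the mean population composition over the distribution
#' of the random environment.
#'
#' @inheritParams expected_over_environment
#' @param times output time grid (steps).
#' @param lineage average the four-compartment model (default) or the
#'   three-compartment one.
#' @return A data.frame with column `t` and one column per compartment.
#' @export
average_trajectories <- function(params, ensemble,
                                 times = seq(0, 60, by = 0.25),
                                 lineage = TRUE) {
  if (inherits(ensemble, "dd_env"))
    ensemble <- build_ensemble(ensemble)
  nodes <- ensemble$nodes
  acc <- NULL
  for (i in seq_len(nrow(nodes))) {
    env_i <- if (is.na(nodes$tau[i])) ensemble$env else
      realize_env(ensemble$env, nodes$tau[i])
    run <- run_ode(params, env = env_i, lineage = lineage, times = times,
                   t_max = max(times), stop_at_saturation = FALSE)
    contrib <- nodes$weight[i] * run$state
    acc <- if (is.null(acc)) contrib else acc + contrib
  }
  data.frame(t = times, acc, check.names = FALSE)
}
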