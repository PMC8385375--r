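#' Model parameters for the damage-response population models
#'
#' Bundles every rate and shape constant of the cell-fate models and validates
#' them at construction. Time is measured in discrete model steps, one step
#' being one unperturbed yeast cell cycle; all hazards are per-step
#' probabilities (used unchanged as continuous-time rates by [run_ode()]).
#'
#' The defaults are the baseline parameter set used throughout the package:
#' an initial pool of 20 000 damaged cells in an environment with carrying
#' capacity 100 000, per-step death probabilities 0.1 (damaged), 0.35
#' (adapted) and 0 (repaired), an adapted-to-repaired transition probability
#' of 0.02, a Gaussian repair window peaking at 0.5 one step after damage,
#' and a logistic adaptation curve with maximum 0.5, slope parameter 3 and
#' half-maximum time 3.886 steps.
#'
#' Construction fails with a single message listing every violated range
#' constraint. The discrete stochastic model additionally requires the
#' per-step fate probabilities of a damaged cell to form a sub-probability
#' vector, `gamma1 + alpha_at(t) + beta_at(t) <= 1` for all `t`; that check
#' ([check_step_probabilities()]) is enforced on entry to the stochastic
#' model only, because the continuous model uses the curves as rates and
#' remains well defined without it.
#'
#' @param N0 initial number of damaged cells (cells).
#' @param Nmax carrying capacity of the environment (cells); must exceed `N0`.
#' @param gamma1 per-step death probability of damaged cells.
#' @param gamma_ad per-step death probability of adapted cells.
#' @param gamma_r per-step death probability of repaired cells.
#' @param delta per-step probability that an adapted cell repairs its damage
#'   (e.g. through an alternative repair pathway in a later cell cycle).
#' @param alpha_m peak repair probability.
#' @param sigma width of the Gaussian repair window (steps).
#' @param mu_a centre of the repair window (steps after damage).
#' @param beta_m maximal adaptation probability.
#' @param p slope parameter of the logistic adaptation curve; the slope at
#'   the half-maximum time is `p * beta_m / 4`.
#' @param mu_b half-maximum time of the adaptation curve (steps after
#'   damage).
#'
#' @return An object of class `dd_params`: a validated named list with the
#'   fields above.
#' @seealso [alpha_at()], [beta_at()], [run_stochastic()], [run_ode()]
#' @examples
#' params <- dd_params()
#' alpha_at(1, params)    # peak repair probability
#' beta_at(3.886, params) # half of beta_m
#' @export
dd_params <- function(N0 = 20000, Nmax = 100000,
                      gamma1 = 0.1, gamma_ad = 0.35, gamma_r = 0,
                      delta = 0.02,
                      alpha_m = 0.5, sigma = 0.5, mu_a = 1,
                      beta_m = 0.5, p = 3, mu_b = 3.886) {
  params <- list(N0 = N0, Nmax = Nmax, gamma1 = gamma1, gamma_ad = gamma_ad,
                 gamma_r = gamma_r, delta = delta, alpha_m = alpha_m,
                 sigma = sigma, mu_a = mu_a, beta_m = beta_m, p = p,
                 mu_b = mu_b)
  params <- lapply(params, function(v) if (is.integer(v)) as.double(v) else v)
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  for (nm in names(params)) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      note(sprintf("'%s' must be a single finite number", nm))
  }
  if (length(problems) == 0L) {
    for (nm in c("gamma1", "gamma_ad", "gamma_r", "delta", "alpha_m",
                 "beta_m")) {
      v <- params[[nm]]
      if (v < 0 || v > 1)
        note(sprintf("'%s' must lie in [0, 1] (got %g)", nm, v))
    }
    if (sigma <= 0) note(sprintf("'sigma' must be > 0 (got %g)", sigma))
    if (p <= 0) note(sprintf("'p' must be > 0 (got %g)", p))
    if (N0 <= 0) note(sprintf("'N0' must be > 0 (got %g)", N0))
    if (Nmax <= 0) note(sprintf("'Nmax' must be > 0 (got %g)", Nmax))
    if (N0 >= Nmax)
      note(sprintf("'N0' must be smaller than 'Nmax' (got %g >= %g)",
                   N0, Nmax))
    if (gamma_ad >= 0 && gamma_ad <= 1 && delta >= 0 && delta <= 1 &&
        gamma_ad + delta > 1 + 1e-12)
      note(sprintf("'gamma_ad' + 'delta' must not exceed 1 (got %g)",
                   gamma_ad + delta))
  }
  if (length(problems) > 0L)
    stop("invalid model parameters:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(params, class = "dd_params")
}

#' Check multinomial validity of a parameter set
#'
#' The discrete stochastic model partitions damaged cells by a multinomial
#' draw with probabilities `(gamma1, beta(n), alpha(n), rest)`, which
#' requires `gamma1 + alpha(t) + beta(t) <= 1` at every step. This holds for
#' the baseline values but can fail when the adaptation and repair windows
#' overlap (e.g. small `mu_b` with large `alpha_m + beta_m`). The check is
#' evaluated at the maximising `t` and enforced by the stochastic model
#' ([markov_step()], [run_stochastic()]); the continuous model treats the
#' curves as rates and has no such constraint, so such parameter sets remain
#' usable with [run_ode()].
#'
#' @param params a [dd_params()] object.
#' @param error throw an error (default) or return `FALSE` on violation.
#' @return `TRUE` if valid, otherwise `FALSE` (or an error).
#' @export
check_step_probabilities <- function(params, error = TRUE) {
  smax <- max_fate_probability(params)
  if (params$gamma1 + smax > 1 + 1e-9) {
    if (error)
      stop(sprintf(paste0("per-step fate probabilities of damaged cells ",
                          "exceed 1: gamma1 + max_t(alpha(t) + beta(t)) ",
                          "= %.6g; this parameter set is not usable with ",
                          "the discrete stochastic model"),
                   params$gamma1 + smax), call. = FALSE)
    return(FALSE)
  }
  TRUE
}

# largest value of alpha(t) + beta(t) over t >= 0 (grid scan + local polish);
# beta is increasing so the supremum includes the t -> Inf limit beta_m
max_fate_probability <- function(params) {
  hi <- max(params$mu_a + 6 * params$sigma, params$mu_b + 40 / params$p)
  grid <- seq(0, hi, length.out = 512L)
  f <- function(t) alpha_at(t, params) + beta_at(t, params)
  vals <- f(grid)
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  up <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(f, c(lo, up), maximum = TRUE, tol = 1e-9)
  max(vals, opt$objective, params$beta_m)
}

#' Time-varying repair and adaptation probabilities
#'
#' `alpha_at()` is the per-step probability that a damaged cell repairs its
#' DNA at time `t` after damage: a Gaussian window
#' `alpha_m * exp(-(t - mu_a)^2 / sigma^2)`, symmetric about `mu_a`.
#' `beta_at()` is the per-step probability that a damaged cell adapts
#' (overrides the checkpoint): a logistic curve
#' `beta_m / (1 + exp(-p * (t - mu_b)))`, increasing in `t` with limit
#' `beta_m` and slope `p * beta_m / 4` at `t = mu_b`.
#'
#' These are per-step probabilities, not densities; their values are also
#' used directly as continuous-time rates in the ODE models.
#'
#' @param t time since the initial damage, in steps; vectorised.
#' @param params a [dd_params()] object.
#' @return Numeric vector of probabilities, same length as `t`.
#' @examples
#' p <- dd_params()
#' alpha_at(c(0, 1, 2), p)
#' beta_at(p$mu_b, p)  # beta_m / 2
#' @export
alpha_at <- function(t, params) {
  params$alpha_m * exp(-(t - params$mu_a)^2 / params$sigma^2)
}

#' @rdname alpha_at
#' @export
beta_at <- function(t, params) {
  params$beta_m / (1 + exp(-params$p * (t - params$mu_b)))
}

#' @export
print.dd_params <- function(x, ...) {
  cat("Cell-fate model parameters (dd_params)\n")
  cat(sprintf("  population:  N0 = %g, Nmax = %g\n", x$N0, x$Nmax))
  cat(sprintf("  death:       gamma1 = %g, gamma_ad = %g, gamma_r = %g\n",
              x$gamma1, x$gamma_ad, x$gamma_r))
  cat(sprintf("  adapted -> repaired: delta = %g\n", x$delta))
  cat(sprintf("  repair curve:     alpha_m = %g, sigma = %g, mu_a = %g\n",
              x$alpha_m, x$sigma, x$mu_a))
  cat(sprintf("  adaptation curve: beta_m = %g, p = %g, mu_b = %g\n",
              x$beta_m, x$p, x$mu_b))
  invisible(x)
}

# apply overrides to a dd_params object, revalidating.
# (the first formal must not have a field name as a prefix, or a named
# override like p = 2 would partial-match it instead of going into `...`)
modify_params <- function(.base, ...) {
  over <- list(...)
  stopifnot(inherits(.base, "dd_params"),
            length(over) == 0 || all(names(over) %in% names(.base)))
  .base[names(over)] <- over
  do.call(dd_params, unclass(.base))
}
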