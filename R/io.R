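#' Load a run configuration
#'
#' Reads a YAML configuration with up to four blocks — `params` (flat
#' key/value pairs named exactly as the [dd_params()] fields),
#' `environment` (the [dd_environment()] fields), `experiment` (`model`,
#' `replicates`, `base_seed`, `t_max`) and `output` (`dir`) — validates it,
#' and fills every omitted entry with the package baseline. An empty (or
#' missing) file therefore yields the pure baseline configuration. Unknown
#' keys are rejected; every invalid or unknown entry is reported in a
#' single error message.
#'
#' @param path path to a YAML file, or `NULL` for the packaged baseline
#'   configuration.
#' @return An object of class `dd_config`: list with elements `params` (a
#'   `dd_params`), `environment` (a `dd_env`), `experiment`, `output`, and
#'   `hash` (see [config_hash()]).
#' @seealso [save_config()], [write_results()]
#' @examples
#' cfg <- load_config()  # packaged baseline
#' cfg$params$mu_b
#' @export
load_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "baseline.yaml", package = "ddadapt",
                        mustWork = TRUE)
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw))
    stop("config must be a YAML mapping", call. = FALSE)

  problems <- character(0)
  known_blocks <- c("params", "environment", "experiment", "output")
  unknown <- setdiff(names(raw), known_blocks)
  if (length(unknown) > 0)
    problems <- c(problems, paste0("unknown top-level key(s): ",
                                   paste(unknown, collapse = ", ")))

  take_block <- function(block, allowed) {
    b <- raw[[block]]
    if (is.null(b)) return(list())
    bad <- setdiff(names(b), allowed)
    if (length(bad) > 0)
      problems <<- c(problems,
                     sprintf("unknown key(s) in '%s': %s", block,
                             paste(bad, collapse = ", ")))
    b[intersect(names(b), allowed)]
  }

  p_args <- take_block("params", names(formals(dd_params)))
  e_args <- take_block("environment", names(formals(dd_environment)))
  x_args <- take_block("experiment",
                       c("model", "replicates", "base_seed", "t_max",
                         "n_nodes"))
  o_args <- take_block("output", "dir")

  params <- tryCatch(do.call(dd_params, p_args), error = function(e) {
    problems <<- c(problems, conditionMessage(e)); NULL
  })
  env <- tryCatch(do.call(dd_environment, e_args), error = function(e) {
    problems <<- c(problems, conditionMessage(e)); NULL
  })
  experiment <- utils::modifyList(
    list(model = "ode", replicates = 10000, base_seed = 1, t_max = 500,
         n_nodes = 200),
    x_args)
  if (!experiment$model %in% c("ode", "stochastic"))
    problems <- c(problems, sprintf("experiment 'model' must be %s",
                                    "'ode' or 'stochastic'"))
  output <- utils::modifyList(list(dir = "."), o_args)

  if (length(problems) > 0)
    stop("invalid configuration (", path, "):\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  cfg <- structure(list(params = params, environment = env,
                        experiment = experiment, output = output),
                   class = "dd_config")
  cfg$hash <- config_hash(cfg)
  cfg
}

#' Write a configuration back to YAML
#'
#' Serialises a [load_config()] object to a YAML file; `load_config()` of
#' the written file round-trips to an identical configuration (and hash).
#'
#' @param config a `dd_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "dd_config"))
  env <- config$environment
  env_fields <- unclass(env)
  env_fields <- env_fields[!vapply(env_fields, is.null, logical(1))]
  yaml::write_yaml(list(params = unclass(config$params),
                        environment = env_fields,
                        experiment = config$experiment,
                        output = config$output),
                   path, precision = 17L)  # lossless double round-trip
  invisible(path)
}

#' Stable hash of a configuration
#'
#' MD5 digest of the canonicalised configuration (keys sorted recursively,
#' values formatted deterministically), so the hash is independent of key
#' order in the source file. Used to stamp result files with the
#' configuration that produced them.
#'
#' @param config a `dd_config` (or any nested list).
#' @return A 32-character hex string.
#' @export
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x))]
      paste0("{", paste(names(x), vapply(x, canon, character(1)),
                        sep = ":", collapse = ","), "}")
    } else {
      paste(format(x, digits = 15), collapse = ",")
    }
  }
  x <- unclass(config)
  x$hash <- NULL
  x$params <- if (!is.null(x$params)) unclass(x$params)
  x$environment <- if (!is.null(x$environment)) unclass(x$environment)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(canon(x), tmp)
  unname(tools::md5sum(tmp))
}

#' Write sweep or trajectory results to disk
#'
#' Writes a CSV with a declared column schema (one row per grid point for
#' sweeps, one row per stored time point for runs) and a JSON summary
#' embedding the package version, the argmin / saturation time, and the
#' configuration hash when one is supplied. Field order is deterministic,
#' so identical inputs produce byte-identical files.
#'
#' @param x a `dd_sweep`, `dd_ode_run` or `dd_stoch_run` object.
#' @param path output path without extension; writes `<path>.csv` and
#'   `<path>.json`.
#' @param config optional `dd_config` whose hash is embedded in the
#'   summary.
#' @return Invisibly, a character vector with the two file paths.
#' @export
write_results <- function(x, path, config = NULL) UseMethod("write_results")

write_result_files <- function(table, summary, path, config) {
  summary$package_version <- as.character(utils::packageVersion("ddadapt"))
  if (!is.null(config)) summary$config_hash <- config_hash(config)
  csv <- paste0(path, ".csv"); json <- paste0(path, ".json")
  utils::write.csv(table, csv, row.names = FALSE)
  jsonlite::write_json(summary, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(csv, json))
}

#' @export
write_results.dd_sweep <- function(x, path, config = NULL) {
  write_result_files(
    x$data,
    list(kind = "sweep", param = x$param, model = x$model,
         argmin = x$argmin, Ts_min = x$Ts_min,
         argmin_refined = x$argmin_refined, Ts_refined = x$Ts_refined,
         n_nonsaturating = x$n_nonsaturating),
    path, config)
}

#' @export
write_results.dd_ode_run <- function(x, path, config = NULL) {
  write_result_files(
    data.frame(t = x$times, x$state, check.names = FALSE),
    list(kind = "ode_run", lineage = x$lineage, Ts = x$Ts,
         saturated = x$saturated,
         rtol = x$diagnostics$rtol, atol = x$diagnostics$atol),
    path, config)
}

#' @export
write_results.dd_stoch_run <- function(x, path, config = NULL) {
  if (is.null(x$trajectory))
    stop("run was simulated with keep_trajectory = FALSE", call. = FALSE)
  write_result_files(
    x$trajectory,
    list(kind = "stochastic_run", Ts = x$Ts, saturated = x$saturated,
         seed = x$seed),
    path, config)
}
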