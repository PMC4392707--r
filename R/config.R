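#' Assemble and validate a run configuration
#'
#' A run configuration bundles input paths, the problem type, its
#' parameters and solver options, and round-trips losslessly through its
#' on-disk YAML form, so analyses can be re-run from a single file.
#' Parameter ranges are validated here, before any solve is attempted.
#'
#' @param problem One of `"reserve"`, `"sweep"`, `"taxonsel"`, `"sd"`.
#' @param inputs Named list of input file paths (e.g. `splits`, `presence`,
#'   `costs`, `boundary`, `foodweb`).
#' @param p,k,d,beta Problem parameters (validated against their ranges).
#' @param ratios Numeric ratio grid for sweeps.
#' @param mode Aggregation mode for tree input, see [aggregate_trees()].
#' @param time_limit Solver time limit in seconds.
#' @param seed Integer seed recorded in result files.
#' @param out Output directory or file.
#' @return A list of class `run_config`.
#' @export
run_config <- function(problem, inputs = list(), p = NULL, k = NULL,
                       d = NULL, beta = NULL, ratios = NULL,
                       mode = "mean", time_limit = 60, seed = NULL,
                       out = NULL) {
  problem <- match.arg(problem, c("reserve", "sweep", "taxonsel", "sd"))
  if (!is.null(p) && (!is.numeric(p) || p < 0 || p > 100)) {
    stop("p must lie in [0, 100]", call. = FALSE)
  }
  if (!is.null(k) && (!is.numeric(k) || k < 0 || k != round(k))) {
    stop("k must be a non-negative integer", call. = FALSE)
  }
  if (!is.null(d) && (!is.numeric(d) || d <= 0 || d > 100)) {
    stop("d must lie in (0, 100]", call. = FALSE)
  }
  if (!is.null(beta) && (!is.numeric(beta) || beta < 0)) {
    stop("beta must be non-negative", call. = FALSE)
  }
  if (!is.null(ratios) &&
      (!is.numeric(ratios) || is.unsorted(ratios) || any(ratios <= 0))) {
    stop("ratios must be a positive ascending grid", call. = FALSE)
  }
  mode <- match.arg(mode, c("mean", "sum", "frequency"))
  structure(
    list(problem = problem, inputs = inputs, p = p, k = k, d = d,
         beta = beta, ratios = ratios, mode = mode,
         time_limit = time_limit,
         seed = if (is.null(seed)) NULL else as.integer(seed), out = out),
    class = "run_config"
  )
}

#' Write a run configuration to YAML
#' @param config A `run_config`.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path Path written by [write_config()].
#' @return A validated `run_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}
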