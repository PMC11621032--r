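# Declarative run configuration: the standard defaults of the fitting
# pipeline in one serializable list. CLI flags override file values.

#' Run configuration
#'
#' Collects the pipeline defaults (seeds, step counts, learning-rate
#' endpoints, guide/model choice, harmonic counts, gene-filter thresholds,
#' posterior sample count, credible-interval percentiles, assumed mean
#' half-life) into a single list that round-trips through YAML without loss.
#'
#' @param ... overrides of the defaults.
#' @return a `cv_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 0L,
    n_steps_manifold = 5000L,
    n_steps_velocity = 10000L,
    lr_start = 0.03,
    lr_end = 0.005,
    clip = Inf,
    guide = "meanfield",
    model = "constant",
    k_harmonics = 1L,
    k_harmonics_omega = 1L,
    epsilon = 5,
    min_mean_u = 0.1,
    min_mean_s = 0.3,
    n_posterior_samples = 500L,
    ci_percentiles = c(5, 95),
    mean_half_life_hours = 1.0,
    relu_floor = 1e-5,
    early_stop = FALSE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "cv_config")
}

#' Write / read a run configuration
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `read_config` returns the `cv_config`; `write_config` the path.
#' @export
write_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("config serialization requires the 'yaml' package")
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("config serialization requires the 'yaml' package")
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}
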