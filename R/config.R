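#' Run configuration
#'
#' Collects every simulator, featurization, classifier and analysis
#' parameter (with package defaults) plus the seed and output directory into
#' one serializable list, so a whole run is reproducible from a single YAML
#' file. `write_run_config()` / `read_run_config()` round-trip the
#' structure identically.
#'
#' @param seed Integer master seed.
#' @param duration_h Recording length per arm, hours.
#' @param sampling_rate Hz.
#' @param out_dir Output directory (`NULL` = return results only).
#' @param treatment A [treatment_effect()] description for the drug arm.
#' @param classifier An [mlp_config()].
#'
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, duration_h = 24, sampling_rate = 250,
                       out_dir = NULL,
                       treatment = treatment_effect(),
                       classifier = mlp_config(seed = seed)) {
  structure(
    list(
      seed = seed, duration_h = duration_h, sampling_rate = sampling_rate,
      out_dir = out_dir,
      treatment = unclass(treatment),
      classifier = unclass(classifier)
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config(
    seed = raw$seed, duration_h = raw$duration_h,
    sampling_rate = raw$sampling_rate, out_dir = raw$out_dir,
    treatment = do.call(treatment_effect, raw$treatment),
    classifier = do.call(mlp_config, raw$classifier)
  )
  cfg
}

# Stable hash of a config (recorded in output files for provenance).
config_hash <- function(config) rlang::hash(unclass(config))
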