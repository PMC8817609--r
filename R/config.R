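#' Default run configuration
#'
#' The resolved configuration of a pipeline run: solver settings, boundary
#' -condition defaults, cohort parameters, and positivity cutoffs. YAML
#' config files override these defaults and command-line flags override
#' the config; every run logs its resolved configuration and seed, so any
#' deterministic command can be reproduced bit-for-bit from the log.
#'
#' @return a nested list of defaults.
#' @export
default_config <- function() {
  list(
    solver = list(step = 0.5, k_e = 1, measurement_offset = 30),
    bc = list(flow_coeff = 3.41, flow_exp = 0.75, murray_exp = 3,
              hyperemic_factor = 3, density = 1056, viscosity = 0.0035),
    cohort = list(n_vessels = 36, sigma_ifr = 0.02, sigma_ffr = 0.03),
    cutoffs = list(index = 0.89, ifr = 0.89, ffr = 0.80),
    seed = 1L
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Load a run configuration
#'
#' Reads a YAML config file (if any) over [default_config()]; the result
#' round-trips losslessly through YAML serialization.
#'
#' @param path YAML file path or `NULL` for pure defaults.
#' @return the resolved configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_invalid("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}
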