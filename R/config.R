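.dfemdt_env <- new.env(parent = emptyenv())

#' Package model configuration
#'
#' Reads the structured-text configuration that ships with the package
#' (standard-man physiology, exposure scenarios, detection limits, BMI
#' population distribution, solver defaults). The file is YAML; users may
#' supply their own file with the same schema.
#'
#' @param path Path to a YAML configuration file. `NULL` (default) uses the
#'   configuration shipped with the package, cached after first read.
#' @return A nested list mirroring the YAML structure.
#' @export
#' @examples
#' cfg <- dfemdt_config()
#' cfg$standard_man$compartments$fat$volume_l
dfemdt_config <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.dfemdt_env$config)) {
      shipped <- system.file("extdata", "dfemdt-config.yaml", package = "dfemdt",
                             mustWork = TRUE)
      .dfemdt_env$config <- yaml::read_yaml(shipped)
    }
    return(.dfemdt_env$config)
  }
  yaml::read_yaml(path)
}

#' Read and write run configurations
#'
#' A run configuration bundles everything needed to reproduce an ensemble run:
#' scenario, population spec, detection limits, iteration count, master seed,
#' and solver settings. It round-trips losslessly through YAML.
#'
#' @param path File path.
#' @param config A run-configuration list, e.g. from [default_run_config()].
#' @return `read_run_config()` returns the configuration list;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' @rdname read_run_config
#' @param scenario Scenario name from the shipped configuration.
#' @param n Number of Monte Carlo iterations.
#' @param seed Master seed.
#' @param solver `"closed_form"` or `"rk4"`.
#' @export
default_run_config <- function(scenario = "Y", n = 1000, seed = 1,
                               solver = "closed_form") {
  cfg <- dfemdt_config()
  list(
    scenario = scenario,
    scenario_def = cfg$scenarios[[scenario]],
    population = cfg$population,
    detection_limits_mg_l = vapply(cfg$detection_limits_mg_l, `[[`, 0, "value"),
    n = n,
    seed = seed,
    solver = solver,
    simulation = cfg$simulation
  )
}
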