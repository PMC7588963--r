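#' Export a trajectory to tidy CSV
#'
#' @param traj A `dfe_trajectory`.
#' @param path Output file.
#' @param subject_id Identifier written into the `subject` column.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, subject_id = 1L) {
  out <- tidy(traj)
  out$subject <- subject_id
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write an MDT summary table as TSV
#'
#' Fixed column order `detection_limit_mg_per_l`, `scenario`, `median_h`,
#' `p5_h`, `p95_h` with times in hours rounded to one decimal.
#'
#' @param mdt A `dfe_mdt_table` (or row-bound tibble of them).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mdt_tsv <- function(mdt, path) {
  out <- tidy(mdt)[, c("detection_limit_mg_per_l", "scenario",
                       "median_h", "p5_h", "p95_h")]
  out$median_h <- round(out$median_h, 1)
  out$p5_h <- round(out$p5_h, 1)
  out$p95_h <- round(out$p95_h, 1)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

run_manifest <- function(config) {
  list(
    package = "dfemdt",
    version = as.character(utils::packageVersion("dfemdt")),
    seed = config$seed,
    n = config$n,
    solver = config$solver,
    scenario = config$scenario,
    config_hash = rlang::hash(config)
  )
}

#' Run a single-subject simulation job from a configuration
#'
#' Simulates one subject (default: the standard man on the configured
#' scenario's central pattern), writes the trajectory CSV and a JSON run
#' manifest (config hash, seed, version) sufficient to reproduce the output
#' exactly.
#'
#' @param config A run configuration, e.g. [default_run_config()].
#' @param out_dir Output directory (created if needed).
#' @param bmi Subject BMI; default the standard man.
#' @return Named list of the written file paths, invisibly.
#' @export
run_simulation_job <- function(config, out_dir, bmi = 24.2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scenario <- exposure_scenario(config$scenario)
  params <- scale_physiology(bmi, config$population$height_m,
                             config$population$workload_w)
  prof <- inhaled_concentration_profile(central_pattern(scenario), scenario)
  traj <- simulate_pbpk(params, prof, solver = config$solver)
  paths <- list(
    trajectory = file.path(out_dir, "trajectory.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_trajectory_csv(traj, paths$trajectory)
  jsonlite::write_json(run_manifest(config), paths$manifest,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Run a Monte Carlo MDT job from a configuration
#'
#' Runs the configured ensemble, summarizes MDTs for every configured
#' detection limit, and writes the summary TSV plus a JSON run manifest.
#'
#' @param config A run configuration, e.g. [default_run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named list with the written paths and the `dfe_mdt_table`,
#'   invisibly.
#' @export
run_mdt_job <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- population_spec(
    bmi_mean = config$population$bmi_mean,
    bmi_sd = config$population$bmi_sd,
    bmi_bounds = unlist(config$population$bmi_bounds),
    height = config$population$height_m,
    workload = config$population$workload_w
  )
  ens <- run_ensemble(config$scenario, n = config$n, spec = spec,
                      seed = config$seed, solver = config$solver)
  mdt <- summarize_mdt(ens, limits = config$detection_limits_mg_l)
  paths <- list(
    mdt_table = file.path(out_dir, "mdt_table.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_mdt_tsv(mdt, paths$mdt_table)
  jsonlite::write_json(run_manifest(config), paths$manifest,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, list(mdt = mdt)))
}
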