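#' Run a Monte Carlo ensemble
#'
#' Samples `n` subjects (BMI and huff pattern), scales the physiology of
#' each, and simulates each subject's venous DFE concentration from the
#' start of the abuse session to `post_horizon_h` hours after it ends. The
#' default solver is the exact closed-form propagator, which keeps
#' 1000-subject ensembles at desk scale. Deterministic given the seed.
#'
#' @param scenario A `dfe_scenario` (or scenario name).
#' @param n Number of subjects; the study design uses 1000.
#' @param spec A `dfe_population`.
#' @param seed Master seed.
#' @param solver Passed to [simulate_pbpk()].
#' @param session_dt_min,post_dt_min Output grid spacing, minutes.
#' @param post_horizon_h Simulated time beyond session end, hours; the
#'   default 72 h covers the last crossing of the lowest detection limit for
#'   every subject the population sampler can produce.
#' @param per_huff Redraw inhalation duration per huff (see
#'   [sample_subjects()]).
#' @return A `dfe_ensemble`: list with the common `time_min` grid, an
#'   `n_time x n` matrix `c_ven` of venous concentrations, the `subjects`
#'   tibble, the scenario, session end, and seed.
#' @export
#' @examples
#' ens <- run_ensemble("Y", n = 5, seed = 7)
#' dim(ens$c_ven)
run_ensemble <- function(scenario, n = 1000, spec = population_spec(),
                         seed = 1, solver = "closed_form",
                         session_dt_min = 0.1, post_dt_min = 1,
                         post_horizon_h = 72, per_huff = FALSE) {
  if (is.character(scenario)) scenario <- exposure_scenario(scenario)
  subjects <- sample_subjects(n, scenario, spec, seed, per_huff = per_huff)
  c_on <- pure_gas_concentration(scenario$ppm)
  t_end <- scenario$session_min + post_horizon_h * 60
  out_times <- sort(unique(c(
    seq(0, scenario$session_min, by = session_dt_min),
    seq(scenario$session_min, t_end, by = post_dt_min), t_end)))

  sim_one <- function(i) {
    row <- subjects[i, ]
    params <- scale_physiology(row$bmi, spec$height, spec$workload)
    starts <- seq(0, scenario$session_min - 1e-9, by = row$cycle_min)
    dur <- if (per_huff) row$huff_durations_s[[1]] else row$inhalation_s
    prof <- structure(
      tibble(start_min = starts, end_min = starts + dur / 60, c_mg_l = c_on),
      class = c("dfe_profile", "tbl_df", "tbl", "data.frame"),
      session_min = scenario$session_min)
    traj <- simulate_pbpk(params, prof, t_end = t_end, out_times = out_times,
                          solver = solver, quantities = "venous")
    traj$c_ven
  }
  conc <- vapply(seq_len(n), sim_one, numeric(length(out_times)))
  structure(
    list(time_min = out_times, c_ven = conc, subjects = subjects,
         scenario = scenario, session_min = scenario$session_min,
         seed = seed, n = n, solver = solver),
    class = "dfe_ensemble"
  )
}

#' @export
print.dfe_ensemble <- function(x, ...) {
  cat(sprintf("<dfe_ensemble> scenario %s, %d subjects, seed %s, %d time points\n",
              x$scenario$name, x$n, format(x$seed), length(x$time_min)))
  invisible(x)
}

#' Maximum detection time of a trajectory
#'
#' The time from the end of the abuse session until the venous blood
#' concentration last falls below the analytical detection limit. The
#' crossing is located by scanning the sampled trajectory from its final
#' point backwards and interpolating between samples linearly in
#' log-concentration (the post-session decay is near-exponential). Returns
#' 0 if the concentration is below the limit at session end and never rises
#' above it again.
#'
#' @param traj A `dfe_trajectory`, or any data frame with `time_min` and
#'   `c_ven` columns.
#' @param limit Detection limit, mg/L blood (> 0).
#' @param session_min Session end, minutes; defaults to the trajectory's
#'   attribute.
#' @return Maximum detection time in hours.
#' @export
maximum_detection_time <- function(traj, limit,
                                   session_min = attr(traj, "session_min")) {
  stopifnot(is.numeric(limit), limit > 0)
  post <- traj$time_min >= session_min - 1e-9
  .mdt_from_series(traj$time_min[post], traj$c_ven[post], limit, session_min)
}

.mdt_from_series <- function(t, v, limit, session_min) {
  nt <- length(t)
  if (v[nt] >= limit) {
    abort("Concentration still at or above the limit at the final sample; extend the simulation horizon.",
          class = "dfemdt_error_horizon")
  }
  above <- which(v >= limit)
  if (length(above) == 0) return(0)
  i <- max(above)
  t1 <- t[i]; t2 <- t[i + 1L]; v1 <- v[i]; v2 <- v[i + 1L]
  t_cross <- if (v2 > 0) {
    t1 + (t2 - t1) * (log(v1) - log(limit)) / (log(v1) - log(v2))
  } else {
    t1 + (t2 - t1) * (v1 - limit) / (v1 - v2)
  }
  max(t_cross - session_min, 0) / 60
}

#' Summarize maximum detection times over an ensemble
#'
#' Per-subject MDTs for each detection limit, summarized as the median and
#' the 5th/95th percentiles (linear-interpolation quantile estimator).
#'
#' @param ensemble A `dfe_ensemble`.
#' @param limits Detection limits, mg/L blood; default the three study
#'   limits 0.018, 0.14 and 5.4.
#' @return A `dfe_mdt_table` tibble with columns `detection_limit_mg_per_l`,
#'   `scenario`, `median_h`, `p5_h`, `p95_h`, `n`, `seed`.
#' @export
summarize_mdt <- function(ensemble, limits = NULL) {
  limits <- limits %||%
    vapply(dfemdt_config()$detection_limits_mg_l, `[[`, 0, "value")
  mdts <- mdt_matrix(ensemble, limits)
  out <- tibble(
    detection_limit_mg_per_l = limits,
    scenario = ensemble$scenario$name,
    median_h = apply(mdts, 2, stats::median),
    p5_h = apply(mdts, 2, quantile, probs = 0.05, names = FALSE),
    p95_h = apply(mdts, 2, quantile, probs = 0.95, names = FALSE),
    n = ensemble$n,
    seed = ensemble$seed
  )
  structure(out, class = c("dfe_mdt_table", class(out)))
}

#' Per-subject MDTs for a set of limits
#'
#' @param ensemble A `dfe_ensemble`.
#' @param limits Detection limits, mg/L blood.
#' @return An `n_subjects x n_limits` matrix of MDTs in hours.
#' @export
mdt_matrix <- function(ensemble, limits) {
  post <- ensemble$time_min >= ensemble$session_min - 1e-9
  t <- ensemble$time_min[post]
  conc <- ensemble$c_ven[post, , drop = FALSE]
  vapply(limits, function(lim) {
    apply(conc, 2, function(v)
      .mdt_from_series(t, v, lim, ensemble$session_min))
  }, numeric(ncol(ensemble$c_ven)))
}

#' Percentile concentration curves of an ensemble
#'
#' Pointwise percentiles across subjects of the smoothed venous
#' concentration. During the session each trajectory is smoothed with a
#' centered moving average (default window 5 min) to eliminate the
#' fluctuations between huffs; after the session the curves are left as is.
#'
#' @param ensemble A `dfe_ensemble`.
#' @param probs Percentile levels.
#' @param smooth_window_min Moving-average window during the session,
#'   minutes; 0 disables smoothing.
#' @return A tibble with columns `time_min`, `percentile`, `c_ven`.
#' @export
percentile_curves <- function(ensemble, probs = c(0.05, 0.5, 0.95),
                              smooth_window_min = 5) {
  conc <- ensemble$c_ven
  t <- ensemble$time_min
  in_session <- t <= ensemble$session_min + 1e-9
  if (smooth_window_min > 0 && sum(in_session) > 2) {
    dt <- stats::median(diff(t[in_session]))
    k <- max(1L, round(smooth_window_min / dt))
    if (k %% 2L == 0L) k <- k + 1L
    if (k > 1L) {
      sm <- stats::filter(conc[in_session, , drop = FALSE], rep(1 / k, k),
                          sides = 2)
      sm <- as.matrix(sm)
      na <- is.na(sm)
      sm[na] <- conc[in_session, , drop = FALSE][na] # keep edges unsmoothed
      conc[in_session, ] <- sm
    }
  }
  qs <- t(apply(conc, 1, quantile, probs = probs, names = FALSE))
  colnames(qs) <- paste0("p", probs * 100)
  as_tibble(cbind(tibble(time_min = t), as_tibble(qs))) |>
    tidyr::pivot_longer(-"time_min", names_to = "percentile",
                        values_to = "c_ven")
}
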