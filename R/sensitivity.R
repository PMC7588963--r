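# Map from conventional parameter labels to model fields. Direct parameters
# perturb the scaled physiology; upstream parameters (BW, BMI, W) perturb the
# anthropometry and propagate through the whole scaling chain.
.sens_direct <- c(
  Vf = "v_fat", Vm = "v_muscle", PCfb = "pc_fat", PCmb = "pc_muscle",
  PCba = "pc_blood_air", Qvrg = "q_vrg", Qliv = "q_liver",
  Qfat = "q_fat", Qalv = "q_alv"
)
.sens_upstream <- c("BW", "BMI", "W")

#' Sensitivity parameter labels
#' @return Character vector of parameter names accepted by
#'   [normalized_sensitivity()].
#' @export
sensitivity_parameters <- function() c(names(.sens_direct), .sens_upstream)

#' Normalized local sensitivity coefficient
#'
#' Ratio between the relative change in venous blood DFE and the relative
#' change in one model parameter: a central finite difference
#' `(C(p(1+delta)) - C(p(1-delta))) / (2 delta C(p))`, with the
#' concentration evaluated at `t_eval_h` hours after the start of a
#' standard-man run of the scenario-Y central huffing pattern. `BW`, `BMI`
#' and `W` are perturbed upstream of physiological scaling (height fixed),
#' so their coefficients include all induced volume and flow changes; the
#' remaining parameters are perturbed directly on the scaled physiology.
#'
#' @param parameter One of [sensitivity_parameters()].
#' @param t_eval_h Evaluation time, hours from session start.
#' @param delta Relative perturbation (default 1%).
#' @param scenario A `dfe_scenario`; default scenario Y.
#' @param bmi,height,workload Baseline anthropometry (standard man).
#' @param solver Passed to [simulate_pbpk()].
#' @return A one-row tibble: `parameter`, `coefficient`, `t_eval_h`,
#'   `delta`.
#' @export
normalized_sensitivity <- function(parameter, t_eval_h = 24, delta = 0.01,
                                   scenario = exposure_scenario("Y"),
                                   bmi = 24.2, height = 1.70, workload = 10,
                                   solver = "closed_form") {
  if (!parameter %in% sensitivity_parameters()) {
    abort(sprintf("Unknown parameter \"%s\"; see sensitivity_parameters().",
                  parameter),
          class = "dfemdt_error_parameter")
  }
  prof <- inhaled_concentration_profile(central_pattern(scenario), scenario)
  c_at <- function(params) {
    traj <- simulate_pbpk(params, prof, t_end = t_eval_h * 60,
                          out_times = t_eval_h * 60, solver = solver,
                          quantities = "venous")
    traj$c_ven[nrow(traj)]
  }
  perturbed <- function(fac) {
    if (parameter %in% .sens_upstream) {
      switch(parameter,
        BMI = scale_physiology(bmi * fac, height, workload),
        BW = scale_physiology(body_weight_from_bmi(bmi, height) * fac / height^2,
                              height, workload),
        W = scale_physiology(bmi, height, workload * fac))
    } else {
      p <- scale_physiology(bmi, height, workload)
      p[[.sens_direct[[parameter]]]] <- p[[.sens_direct[[parameter]]]] * fac
      p
    }
  }
  c0 <- c_at(perturbed(1))
  if (c0 <= 0) {
    abort("Baseline concentration is zero at the evaluation time.",
          class = "dfemdt_error_sensitivity")
  }
  cp <- c_at(perturbed(1 + delta))
  cm <- c_at(perturbed(1 - delta))
  tibble(parameter = parameter, coefficient = (cp - cm) / (2 * delta * c0),
         t_eval_h = t_eval_h, delta = delta)
}

#' Local sensitivity analysis of late blood DFE
#'
#' Computes normalized sensitivity coefficients for all (or a chosen subset
#' of) model parameters, sorted by absolute magnitude. By convention,
#' parameters with |coefficient| below `threshold` (default 0.1) can be
#' filtered out when mirroring the published presentation.
#'
#' @param parameters Parameter labels; default all of
#'   [sensitivity_parameters()].
#' @param filter_threshold Keep only |coefficient| >= this value; `0`
#'   disables filtering.
#' @inheritParams normalized_sensitivity
#' @return A `dfe_sensitivity` tibble sorted by decreasing |coefficient|.
#' @export
sensitivity_analysis <- function(parameters = sensitivity_parameters(),
                                 t_eval_h = 24, delta = 0.01,
                                 scenario = exposure_scenario("Y"),
                                 filter_threshold = 0, solver = "closed_form") {
  out <- purrr::map(parameters, normalized_sensitivity, t_eval_h = t_eval_h,
                    delta = delta, scenario = scenario, solver = solver) |>
    bind_rows() |>
    dplyr::filter(abs(.data$coefficient) >= filter_threshold) |>
    arrange(dplyr::desc(abs(.data$coefficient)))
  structure(out, class = c("dfe_sensitivity", class(out)))
}
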