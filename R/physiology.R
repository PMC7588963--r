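#' Body weight from body mass index
#'
#' BMI is defined as body weight over height squared; at fixed height the
#' inverse relation gives the weight of a subject with a given BMI. Used to
#' turn sampled BMI values into the body weights that drive physiological
#' scaling (height is held at 1.70 m in the study configuration).
#'
#' @param bmi Body mass index, kg/m^2. Vectorized.
#' @param height Height, m.
#' @return Body weight in kg (`bmi * height^2`).
#' @export
#' @examples
#' body_weight_from_bmi(24.2, 1.70) # ~69.9 kg, the 70-kg standard man
body_weight_from_bmi <- function(bmi, height) {
  if (any(!is.finite(bmi)) || any(bmi <= 0) ||
      any(!is.finite(height)) || any(height <= 0)) {
    abort("`bmi` and `height` must be finite and strictly positive.",
          class = "dfemdt_error_anthropometry")
  }
  bmi * height^2
}

#' Standard-man physiology
#'
#' Reference parameterization of the five-compartment PBPK model for a
#' resting adult male (70 kg, 1.70 m, BMI 24.2) at near rest (10 W):
#' compartment volumes, blood flows, alveolar ventilation, cardiac output and
#' partition coefficients. All values come verbatim from the shipped
#' configuration file.
#'
#' @return An object of class `dfe_physiology`: a named list with fields
#'   `v_lung`, `v_vrg`, `v_fat`, `v_muscle`, `v_liver` (L), `q_alv`, `q_co`,
#'   `q_vrg`, `q_fat`, `q_muscle`, `q_liver` (L/min), `pc_blood_air`,
#'   `pc_lung`, `pc_vrg`, `pc_fat`, `pc_muscle`, `pc_liver` (dimensionless),
#'   `workload` (W), plus `bmi`, `height`, `body_weight` metadata.
#' @export
#' @examples
#' standard_man()$v_fat # 15.43 L
standard_man <- function() {
  sm <- dfemdt_config()$standard_man
  cp <- sm$compartments
  new_physiology(
    v_lung = cp$lung_arterial$volume_l, v_vrg = cp$vrg$volume_l,
    v_fat = cp$fat$volume_l, v_muscle = cp$muscle$volume_l,
    v_liver = cp$liver$volume_l,
    q_alv = sm$alveolar_ventilation_l_min, q_co = sm$cardiac_output_l_min,
    q_vrg = cp$vrg$flow_l_min, q_fat = cp$fat$flow_l_min,
    q_muscle = cp$muscle$flow_l_min, q_liver = cp$liver$flow_l_min,
    pc_blood_air = sm$pc_blood_air,
    pc_lung = cp$lung_arterial$pc_tissue_blood,
    pc_vrg = cp$vrg$pc_tissue_blood, pc_fat = cp$fat$pc_tissue_blood,
    pc_muscle = cp$muscle$pc_tissue_blood, pc_liver = cp$liver$pc_tissue_blood,
    workload = sm$workload_w,
    bmi = sm$bmi_kg_m2, height = sm$height_m,
    body_weight = body_weight_from_bmi(sm$bmi_kg_m2, sm$height_m)
  )
}

new_physiology <- function(...) {
  p <- list(...)
  num <- unlist(p[setdiff(names(p), "workload")])
  if (any(!is.finite(num)) || any(num <= 0)) {
    abort("All physiological volumes, flows and partition coefficients must be positive.",
          class = "dfemdt_error_physiology")
  }
  structure(p, class = "dfe_physiology")
}

#' @export
print.dfe_physiology <- function(x, ...) {
  cat(sprintf("<dfe_physiology> BMI %.1f, height %.2f m, BW %.1f kg, workload %g W\n",
              x$bmi, x$height, x$body_weight, x$workload))
  cat(sprintf("  volumes (L): lung %.2f, vrg %.2f, fat %.2f, muscle %.2f, liver %.2f\n",
              x$v_lung, x$v_vrg, x$v_fat, x$v_muscle, x$v_liver))
  cat(sprintf("  flows (L/min): alv %.2f, co %.2f, vrg %.2f, fat %.2f, muscle %.2f, liver %.2f\n",
              x$q_alv, x$q_co, x$q_vrg, x$q_fat, x$q_muscle, x$q_liver))
  invisible(x)
}

#' @method as_tibble dfe_physiology
#' @export
as_tibble.dfe_physiology <- function(x, ...) {
  tibble(parameter = names(unlist(x)), value = unname(unlist(x)))
}

#' Scale physiology from anthropometry
#'
#' Scales the standard-man compartment volumes and blood flows to a subject
#' of given BMI, height, and physical workload. Body fat mass follows a
#' linear body-fat-fraction relation in BMI (anchored so that BMI 24.2 at
#' 1.70 m reproduces the reference fat volume exactly); lean-tissue volumes
#' scale in proportion to lean body mass; cardiac output and alveolar
#' ventilation scale with lean body mass to the 3/4 power; tissue blood flows
#' stay fixed fractions of cardiac output, so the fat washout time constant
#' grows with BMI. Workload above rest adds ventilation and cardiac output
#' linearly, routed to muscle. Partition coefficients are
#' substance properties and do not scale.
#'
#' At the standard man (BMI 24.2, 1.70 m, 10 W) the output equals
#' [standard_man()] exactly.
#'
#' @param bmi Body mass index, kg/m^2; must lie in the model's validated
#'   range (10, 60).
#' @param height Height, m.
#' @param workload Physical workload, W (>= 0).
#' @return A `dfe_physiology` object.
#' @export
#' @examples
#' scale_physiology(30, 1.70, 10)$v_fat # > 15.43 L
scale_physiology <- function(bmi, height = 1.70, workload = 10) {
  cfg <- dfemdt_config()
  rng <- cfg$scaling$bmi_model_range
  if (!is.finite(bmi) || bmi <= rng[1] || bmi >= rng[2]) {
    abort(sprintf("`bmi` = %s is outside the model's validated range (%g, %g).",
                  format(bmi), rng[1], rng[2]),
          class = "dfemdt_error_bmi_range")
  }
  if (!is.finite(workload) || workload < 0) {
    abort("`workload` must be non-negative.", class = "dfemdt_error_anthropometry")
  }
  ref <- standard_man()
  sc <- cfg$scaling
  rho <- sc$fat_density_kg_l
  slope <- sc$fat_fraction_slope_per_bmi

  bw <- body_weight_from_bmi(bmi, height)
  bw_ref <- ref$body_weight
  # intercept solved so the standard man is exact
  ff_ref <- ref$v_fat * rho / bw_ref
  intercept <- ff_ref - slope * ref$bmi
  ff <- slope * bmi + intercept
  if (ff <= 0 || ff >= 1) {
    abort("Body fat fraction out of (0, 1) for these anthropometrics.",
          class = "dfemdt_error_anthropometry")
  }
  fat_mass <- ff * bw
  v_fat <- fat_mass / rho
  lbm <- bw - fat_mass
  lbm_ref <- bw_ref - ref$v_fat * rho
  lin <- lbm / lbm_ref
  s <- lin^sc$lean_flow_exponent
  dW <- sc$workload_flow_slope_l_min_per_w * (workload - ref$workload)

  new_physiology(
    v_lung = ref$v_lung * lin, v_vrg = ref$v_vrg * lin, v_fat = v_fat,
    v_muscle = ref$v_muscle * lin, v_liver = ref$v_liver * lin,
    q_alv = ref$q_alv * s + dW, q_co = ref$q_co * s + dW,
    q_vrg = ref$q_vrg * s, q_fat = ref$q_fat * s,
    q_muscle = ref$q_muscle * s + dW, q_liver = ref$q_liver * s,
    pc_blood_air = ref$pc_blood_air, pc_lung = ref$pc_lung,
    pc_vrg = ref$pc_vrg, pc_fat = ref$pc_fat,
    pc_muscle = ref$pc_muscle, pc_liver = ref$pc_liver,
    workload = workload, bmi = bmi, height = height, body_weight = bw
  )
}

#' Compartment washout time constant
#'
#' The perfusion-limited washout time constant of a tissue compartment,
#' V x P / Q: tissue volume times tissue:blood partition coefficient over
#' compartment blood flow. It sets the exponential decline rate of that
#' tissue's contribution to blood concentration after exposure ends. For the
#' standard man this gives about 0.8 min for the rapidly perfused organs and
#' liver, and about 3.0 h for fat, which dominates the terminal phase.
#'
#' @param params A `dfe_physiology` object.
#' @param compartment One of `"vrg"`, `"fat"`, `"muscle"`, `"liver"`.
#' @return Time constant in minutes.
#' @export
#' @examples
#' washout_time_constant(standard_man(), "fat") / 60 # ~3.0 h
washout_time_constant <- function(params, compartment) {
  ok <- c("vrg", "fat", "muscle", "liver")
  if (length(compartment) != 1L || !compartment %in% ok) {
    abort(sprintf("`compartment` must be one of %s.",
                  paste0('"', ok, '"', collapse = ", ")),
          class = "dfemdt_error_compartment")
  }
  params[[paste0("v_", compartment)]] *
    params[[paste0("pc_", compartment)]] /
    params[[paste0("q_", compartment)]]
}
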