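#' Population specification
#'
#' Distributional assumptions for the simulated adult-male population: BMI
#' is normal with mean 25.8 and SD 3.43 kg/m^2 (fitted to NHANES III
#' demographic data on American men), truncated to [16.5, 40] to avoid
#' unrealistic values; height is fixed at 1.70 m and workload at 10 W.
#'
#' @param bmi_mean,bmi_sd Normal parameters of BMI, kg/m^2.
#' @param bmi_bounds Length-2 truncation interval, kg/m^2.
#' @param height Height, m.
#' @param workload Physical workload, W.
#' @return A `dfe_population` object.
#' @export
population_spec <- function(bmi_mean = NULL, bmi_sd = NULL, bmi_bounds = NULL,
                            height = NULL, workload = NULL) {
  def <- dfemdt_config()$population
  spec <- list(
    bmi_mean = bmi_mean %||% def$bmi_mean,
    bmi_sd = bmi_sd %||% def$bmi_sd,
    bmi_bounds = bmi_bounds %||% unlist(def$bmi_bounds),
    height = height %||% def$height_m,
    workload = workload %||% def$workload_w
  )
  if (spec$bmi_sd <= 0 || spec$bmi_bounds[1] >= spec$bmi_bounds[2] ||
      spec$bmi_mean < spec$bmi_bounds[1] || spec$bmi_mean > spec$bmi_bounds[2]) {
    abort("Population spec needs sd > 0 and truncation bounds bracketing the mean.",
          class = "dfemdt_error_population")
  }
  structure(spec, class = "dfe_population")
}

#' Sample BMI values from the truncated-normal population
#'
#' Rejection sampling from the truncated normal: redraw any value outside
#' the truncation bounds (acceptance probability ~0.997 for the default
#' parameters). Deterministic given the RNG state.
#'
#' @param n Number of draws.
#' @param spec A `dfe_population`.
#' @return Numeric vector of BMI values within the truncation bounds.
#' @export
#' @examples
#' set.seed(1); range(sample_bmi(1000)) # within [16.5, 40]
sample_bmi <- function(n, spec = population_spec()) {
  x <- rnorm(n, spec$bmi_mean, spec$bmi_sd)
  bad <- which(x < spec$bmi_bounds[1] | x > spec$bmi_bounds[2])
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), spec$bmi_mean, spec$bmi_sd)
    bad <- bad[x[bad] < spec$bmi_bounds[1] | x[bad] > spec$bmi_bounds[2]]
  }
  x
}

#' Closed-form mean of the truncated BMI distribution
#'
#' Standard truncated-normal mean,
#' mu + sigma (phi(alpha) - phi(beta)) / (Phi(beta) - Phi(alpha)), used as
#' the analytic reference for the sampler.
#'
#' @param spec A `dfe_population`.
#' @return Mean BMI of the truncated distribution, kg/m^2 (~25.83 for the
#'   default parameters).
#' @export
truncated_bmi_mean <- function(spec = population_spec()) {
  a <- (spec$bmi_bounds[1] - spec$bmi_mean) / spec$bmi_sd
  b <- (spec$bmi_bounds[2] - spec$bmi_mean) / spec$bmi_sd
  spec$bmi_mean + spec$bmi_sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

#' Sample simulated subjects for a scenario
#'
#' Draws `n` subjects, each defined by a BMI from the truncated-normal
#' population and one huff pattern with inhalation duration and cycle length
#' drawn uniformly from the scenario's ranges. Inhalation parameters are
#' sampled once per subject and held constant over the whole session
#' (between-subject variability); set `per_huff = TRUE` to instead redraw
#' the window length for every huff (exploratory mode; the cycle grid stays
#' fixed at the subject's own draw).
#'
#' The whole table is a pure function of `(spec, scenario, seed)`: one
#' seeded RNG stream drives all draws in subject order.
#'
#' @param n Number of subjects.
#' @param scenario A `dfe_scenario`.
#' @param spec A `dfe_population`.
#' @param seed Master seed (integer).
#' @param per_huff Logical; redraw inhalation duration per huff.
#' @return A tibble with columns `subject`, `bmi`, `body_weight`,
#'   `inhalation_s`, `cycle_min`, and (if `per_huff`) a list-column of
#'   per-huff durations.
#' @export
#' @examples
#' sample_subjects(3, exposure_scenario("Y"), seed = 42)
sample_subjects <- function(n, scenario, spec = population_spec(), seed = 1,
                            per_huff = FALSE) {
  stopifnot(n >= 1)
  withr_seed <- function(code) { # keep the caller's RNG state untouched
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    code
  }
  withr_seed({
    out <- tibble(
      subject = seq_len(n),
      bmi = sample_bmi(n, spec),
      inhalation_s = runif(n, scenario$inhalation_s[1], scenario$inhalation_s[2]),
      cycle_min = runif(n, scenario$cycle_min[1], scenario$cycle_min[2])
    )
    out$body_weight <- body_weight_from_bmi(out$bmi, spec$height)
    out <- out[, c("subject", "bmi", "body_weight", "inhalation_s", "cycle_min")]
    if (per_huff) {
      out$huff_durations_s <- map(out$cycle_min, function(cy) {
        k <- length(seq(0, scenario$session_min - 1e-9, by = cy))
        runif(k, scenario$inhalation_s[1], scenario$inhalation_s[2])
      })
    }
    out
  })
}
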