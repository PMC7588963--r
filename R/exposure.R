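#' Exposure scenarios
#'
#' An exposure scenario describes a huffing session: inhaled concentration
#' (ppm of the pure gas), total session duration, and the uniform ranges for
#' the per-subject inhalation duration and inhalation cycle. Two scenarios
#' ship with the package, derived from interviews about typical air-duster
#' abuse sessions: scenario X (6-h session, 1.5-8 s inhalations every 3-5
#' min) and scenario Y (2-h session, 5-15 s inhalations every 2-5 min), both
#' with essentially 100% DFE (1,000,000 ppm). The stated inhalation window
#' merges the inhalation proper with the subsequent breath-hold.
#'
#' @param name Scenario name in the shipped configuration (`"X"` or `"Y"`),
#'   ignored when all numeric arguments are supplied.
#' @param ppm Inhaled concentration, ppm (0 to 1e6).
#' @param session_h Session duration, hours.
#' @param inhalation_s Length-2 numeric, uniform range of inhalation
#'   duration in seconds.
#' @param cycle_min Length-2 numeric, uniform range of the inhalation cycle
#'   in minutes.
#' @return A `dfe_scenario` object.
#' @export
#' @examples
#' exposure_scenario("Y")
exposure_scenario <- function(name = NULL, ppm = NULL, session_h = NULL,
                              inhalation_s = NULL, cycle_min = NULL) {
  if (!is.null(name) && is.null(ppm)) {
    def <- dfemdt_config()$scenarios[[name]]
    if (is.null(def)) {
      abort(sprintf("Unknown scenario \"%s\".", name),
            class = "dfemdt_error_scenario")
    }
    ppm <- def$inhaled_concentration_ppm
    session_h <- def$session_duration_h
    inhalation_s <- unlist(def$inhalation_duration_s)
    cycle_min <- unlist(def$cycle_min)
  }
  stopifnot(length(inhalation_s) == 2L, length(cycle_min) == 2L)
  if (any(inhalation_s <= 0) || any(cycle_min <= 0) ||
      inhalation_s[1] > inhalation_s[2] || cycle_min[1] > cycle_min[2]) {
    abort("Scenario ranges must be positive with min <= max.",
          class = "dfemdt_error_scenario")
  }
  if (inhalation_s[2] / 60 >= cycle_min[1]) {
    abort("Maximum inhalation duration must be shorter than the minimum cycle.",
          class = "dfemdt_error_scenario")
  }
  structure(
    list(name = name %||% "custom", ppm = ppm, session_h = session_h,
         session_min = session_h * 60,
         inhalation_s = inhalation_s, cycle_min = cycle_min),
    class = "dfe_scenario"
  )
}

#' @export
print.dfe_scenario <- function(x, ...) {
  cat(sprintf(
    "<dfe_scenario %s> %s ppm, %g h session, inhalations %g-%g s every %g-%g min\n",
    x$name, format(x$ppm, big.mark = ","), x$session_h,
    x$inhalation_s[1], x$inhalation_s[2], x$cycle_min[1], x$cycle_min[2]))
  invisible(x)
}

#' Concentration of a gas in air from ppm
#'
#' Converts a volume mixing ratio in ppm to a mass concentration in mg/L of
#' air, using the ideal-gas molar volume at 25 degrees C and 1 atm. For pure
#' DFE (1,000,000 ppm, MW 66.05 g/mol, 24.45 L/mol) this gives 2701.4 mg/L.
#'
#' @param ppm Mixing ratio, parts per million by volume (0 to 1e6).
#' @param mw Molecular weight, g/mol.
#' @param molar_volume Molar volume of the gas phase, L/mol.
#' @return Concentration in mg per L of air.
#' @export
pure_gas_concentration <- function(ppm,
                                   mw = dfemdt_config()$substance$molecular_weight_g_mol,
                                   molar_volume = dfemdt_config()$substance$molar_volume_l_mol) {
  if (any(!is.finite(ppm)) || any(ppm < 0) || any(ppm > 1e6)) {
    abort("`ppm` must lie in [0, 1e6].", class = "dfemdt_error_ppm")
  }
  ppm / 1e6 * mw / molar_volume * 1000
}

#' Huff patterns
#'
#' One realized inhalation pattern: a fixed inhalation duration and cycle
#' length repeated for the whole session. The first huff starts at t = 0 and
#' huffs whose start time falls before the session end are included in full.
#'
#' @param inhalation_s Inhalation (plus breath-hold) duration, seconds.
#' @param cycle_min Time between the starts of successive huffs, minutes.
#' @param session_h Session duration, hours.
#' @return A `dfe_pattern` object.
#' @export
huff_pattern <- function(inhalation_s, cycle_min, session_h) {
  if (inhalation_s <= 0 || cycle_min <= 0 || session_h <= 0 ||
      inhalation_s >= cycle_min * 60) {
    abort("Need 0 < inhalation < cycle and a positive session duration.",
          class = "dfemdt_error_pattern")
  }
  structure(list(inhalation_s = inhalation_s, cycle_min = cycle_min,
                 session_h = session_h, session_min = session_h * 60),
            class = "dfe_pattern")
}

#' @export
print.dfe_pattern <- function(x, ...) {
  cat(sprintf("<dfe_pattern> %g-s huff every %g min for %g h\n",
              x$inhalation_s, x$cycle_min, x$session_h))
  invisible(x)
}

#' Central huff pattern of a scenario
#'
#' The midpoint of each uniform range: 10-s inhalations every 3.5 min for
#' scenario Y, 4.75-s inhalations every 4 min for scenario X. Used for the
#' single-subject (deterministic) simulations.
#'
#' @param scenario A `dfe_scenario`.
#' @return A `dfe_pattern`.
#' @export
#' @examples
#' central_pattern(exposure_scenario("Y")) # 10 s every 3.5 min
central_pattern <- function(scenario) {
  huff_pattern(mean(scenario$inhalation_s), mean(scenario$cycle_min),
               scenario$session_h)
}

#' Inhaled-concentration profile
#'
#' Turns a huff pattern into a piecewise-constant (square-wave) inhaled
#' concentration: the scenario's pure-gas concentration during each huff
#' window `[k * cycle, k * cycle + duration)` for every `k` with
#' `k * cycle < session`, and zero elsewhere (including after the session).
#'
#' @param pattern A `dfe_pattern`.
#' @param scenario A `dfe_scenario` (supplies the ppm level), or `NULL` to
#'   pass `c_mg_l` directly.
#' @param c_mg_l Inhaled concentration during huffs, mg/L air; overrides
#'   `scenario`.
#' @return A `dfe_profile`: a tibble of huff windows with columns
#'   `start_min`, `end_min`, `c_mg_l`, carrying the session duration as an
#'   attribute. Window boundaries are the exposure switch times the solver
#'   must not straddle.
#' @export
#' @examples
#' pr <- inhaled_concentration_profile(central_pattern(exposure_scenario("Y")),
#'                                     exposure_scenario("Y"))
#' nrow(pr) # 35 huff windows in 2 h
inhaled_concentration_profile <- function(pattern, scenario = NULL,
                                          c_mg_l = NULL) {
  if (is.null(c_mg_l)) {
    if (is.null(scenario)) {
      abort("Supply either `scenario` or `c_mg_l`.", class = "dfemdt_error_profile")
    }
    c_mg_l <- pure_gas_concentration(scenario$ppm)
  }
  dur_min <- pattern$inhalation_s / 60
  starts <- seq(0, pattern$session_min - 1e-9, by = pattern$cycle_min)
  out <- tibble(start_min = starts, end_min = starts + dur_min,
                c_mg_l = c_mg_l)
  structure(out, class = c("dfe_profile", class(out)),
            session_min = pattern$session_min, pattern = pattern)
}

#' Inhaled concentration at given times
#'
#' @param profile A `dfe_profile`.
#' @param t_min Times, minutes. Vectorized.
#' @return Concentration in mg/L air at each time.
#' @export
profile_concentration <- function(profile, t_min) {
  i <- findInterval(t_min, profile$start_min)
  inside <- i >= 1 & t_min < profile$end_min[pmax(i, 1L)]
  ifelse(inside, profile$c_mg_l[pmax(i, 1L)], 0)
}

#' Constant exposure window
#'
#' A degenerate profile with a single exposure window starting at t = 0,
#' useful for steady-state checks and chamber-style exposures.
#'
#' @param c_mg_l Inhaled concentration, mg/L air.
#' @param duration_min Window length, minutes (also taken as the session
#'   duration).
#' @return A `dfe_profile`.
#' @export
constant_exposure <- function(c_mg_l, duration_min) {
  out <- tibble(start_min = 0, end_min = duration_min, c_mg_l = c_mg_l)
  structure(out, class = c("dfe_profile", class(out)),
            session_min = duration_min, pattern = NULL)
}

# Full alternating segmentation of [0, t_end] implied by a profile:
# columns t0, t1, c. Used by the solvers; every switch time is a boundary.
profile_segments <- function(profile, t_end) {
  brk <- sort(unique(c(0, profile$start_min, profile$end_min, t_end)))
  brk <- brk[brk <= t_end + 1e-12]
  if (max(brk) < t_end) brk <- c(brk, t_end)
  t0 <- brk[-length(brk)]
  t1 <- brk[-1]
  mid <- (t0 + t1) / 2
  tibble(t0 = t0, t1 = t1, c = profile_concentration(profile, mid))
}
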