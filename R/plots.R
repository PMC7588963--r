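#' Plot a simulated trajectory
#'
#' Mixed-venous blood concentration against time; log concentration scale by
#' default since the post-session decline spans orders of magnitude.
#'
#' @param object A `dfe_trajectory`.
#' @param log_y Use a log10 concentration axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dfe_trajectory
#' @export
autoplot.dfe_trajectory <- function(object, log_y = TRUE, ...) {
  dat <- dplyr::filter(tidy(object), .data$c_ven > 0 | !log_y)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_min / 60,
                                         y = .data$c_ven)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (h)", y = "DFE in mixed venous blood (mg/L)") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot ensemble percentile curves
#'
#' Median and outer percentile venous concentration curves of a Monte Carlo
#' ensemble, with the blood detection limits as horizontal reference lines.
#'
#' @param object A `dfe_ensemble`.
#' @param probs Percentiles to draw.
#' @param smooth_window_min Session smoothing window, minutes.
#' @param limits Detection limits drawn as horizontal lines; `NULL` for
#'   none.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dfe_ensemble
#' @export
autoplot.dfe_ensemble <- function(object, probs = c(0.05, 0.5, 0.95),
                                  smooth_window_min = 5, limits = NULL, ...) {
  limits <- limits %||%
    vapply(dfemdt_config()$detection_limits_mg_l, `[[`, 0, "value")
  curves <- percentile_curves(object, probs, smooth_window_min)
  curves <- dplyr::filter(curves, .data$c_ven > 0)
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$time_min / 60,
                                            y = .data$c_ven,
                                            linetype = .data$percentile)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (h)", y = "DFE in mixed venous blood (mg/L)",
                  linetype = "Percentile") +
    ggplot2::theme_minimal()
  if (length(limits)) {
    p <- p + ggplot2::geom_hline(yintercept = limits, colour = "grey50",
                                 linewidth = 0.3)
  }
  p
}

#' Plot sensitivity coefficients
#'
#' Horizontal bar chart of normalized sensitivity coefficients sorted by
#' magnitude.
#'
#' @param object A `dfe_sensitivity`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dfe_sensitivity
#' @export
autoplot.dfe_sensitivity <- function(object, ...) {
  dat <- tidy(object)
  dat$parameter <- stats::reorder(dat$parameter, abs(dat$coefficient))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$coefficient,
                                    y = .data$parameter)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Normalized sensitivity coefficient", y = NULL) +
    ggplot2::theme_minimal()
}
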