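#' Tidiers for dfemdt result objects
#'
#' broom-style `tidy()` and `glance()` methods. `tidy()` returns the
#' observation-level tibble (long format for ensembles); `glance()` returns
#' a one-row summary.
#'
#' @param x A dfemdt result object.
#' @param ... Unused.
#' @name dfemdt-tidiers
NULL

#' @rdname dfemdt-tidiers
#' @method tidy dfe_trajectory
#' @export
tidy.dfe_trajectory <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' @rdname dfemdt-tidiers
#' @method glance dfe_trajectory
#' @export
glance.dfe_trajectory <- function(x, ...) {
  tibble(
    n_times = nrow(x),
    session_min = attr(x, "session_min"),
    peak_c_ven = max(x$c_ven),
    session_avg_c_ven = session_average(x),
    mass_balance_error = tryCatch(mass_balance_error(x),
                                  error = function(e) NA_real_),
    solver = attr(x, "solver")
  )
}

#' @rdname dfemdt-tidiers
#' @method tidy dfe_ensemble
#' @export
tidy.dfe_ensemble <- function(x, ...) {
  tibble(
    time_min = rep(x$time_min, times = x$n),
    subject = rep(x$subjects$subject, each = length(x$time_min)),
    c_ven = as.vector(x$c_ven)
  )
}

#' @rdname dfemdt-tidiers
#' @method glance dfe_ensemble
#' @export
glance.dfe_ensemble <- function(x, ...) {
  tibble(scenario = x$scenario$name, n = x$n, seed = x$seed,
         session_min = x$session_min, solver = x$solver,
         mean_bmi = mean(x$subjects$bmi))
}

#' @rdname dfemdt-tidiers
#' @method tidy dfe_mdt_table
#' @export
tidy.dfe_mdt_table <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' @rdname dfemdt-tidiers
#' @method tidy dfe_sensitivity
#' @export
tidy.dfe_sensitivity <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' @rdname dfemdt-tidiers
#' @method glance dfe_sensitivity
#' @export
glance.dfe_sensitivity <- function(x, ...) {
  top <- x$parameter[which.max(abs(x$coefficient))]
  tibble(n_parameters = nrow(x), top_parameter = top,
         t_eval_h = x$t_eval_h[1], delta = x$delta[1])
}
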