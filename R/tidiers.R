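# broom-style tidy()/glance() methods for the package's fit objects.

#' @describeIn fit_exponential Parameter estimates as a tibble.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.exp_fit <- function(x, ...) {
  tibble(
    term = c("rate_s", "amplitude", "offset"),
    estimate = c(x$rate_s, x$amplitude, x$offset),
    std.error = c(x$rate_se, x$amplitude_se, x$offset_se)
  )
}

#' @describeIn fit_exponential One-row fit summary.
#' @export
glance.exp_fit <- function(x, ...) {
  tibble(rate_s = x$rate_s, rate_min = per_minute(x$rate_s),
         deviance = x$deviance, nobs = x$n,
         converged = x$converged, flag = x$flag)
}

#' @describeIn fit_aminolysis Parameter estimates as a tibble.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.aminolysis_fit <- function(x, ...) {
  tibble(
    term = c("kcat1", "kcat2"),
    estimate = c(x$kcat1, x$kcat2),
    std.error = c(x$kcat1_se, x$kcat2_se)
  )
}

#' @describeIn fit_aminolysis One-row fit summary.
#' @export
glance.aminolysis_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = nrow(x$data), pH = x$pH, pKa = x$pKa)
}

#' @describeIn fit_kd Parameter estimates (KD and per-residue saturating
#'   CSPs) as a tibble.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.kd_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = "kd_M", estimate = x$kd_M, std.error = x$kd_se_M),
    tibble(term = paste0("dd_max[", x$dd_max$residue, "]"),
           estimate = x$dd_max$dd_max_ppm, std.error = NA_real_)
  )
}

#' @describeIn fit_kd One-row fit summary.
#' @export
glance.kd_fit <- function(x, ...) {
  tibble(kd_uM = x$kd_M * 1e6, kd_se_uM = x$kd_se_M * 1e6, mode = x$mode,
         n_residues = nrow(x$dd_max), ssr = x$ssr, flag = x$flag)
}

#' @describeIn fit_exchange Parameter estimates as a tibble.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.exchange_fit <- function(x, ...) {
  tibble(
    term = c("kon", "koff", "kd_M", "shift_free_hz", "shift_bound_hz",
             "r2_free", "r2_bound"),
    estimate = c(x$kon, x$koff, x$kd_M, x$shift_free_hz, x$shift_bound_hz,
                 x$r2_free, x$r2_bound),
    std.error = c(NA, x$koff_se, x$kd_se_M, NA, NA, NA, NA)
  )
}

#' @describeIn fit_exchange One-row fit summary.
#' @export
glance.exchange_fit <- function(x, ...) {
  tibble(kon = x$kon, koff = x$koff, kd_uM = x$kd_M * 1e6,
         ssr = x$ssr, flag = x$flag)
}

#' @describeIn fit_kub2 Parameter estimate as a tibble.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.kub2_fit <- function(x, ...) {
  tibble(term = "k_ub2", estimate = x$k_ub2, std.error = x$k_ub2_se)
}

#' @describeIn fit_kub2 One-row fit summary.
#' @export
glance.kub2_fit <- function(x, ...) {
  tibble(k_ub2 = x$k_ub2, k_ub2_se = x$k_ub2_se, ssr = x$ssr,
         nobs = x$n, flag = x$flag)
}

#' @describeIn fit_correlation Parameter estimates as a tibble.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.corr_fit <- function(x, ...) {
  tibble(
    term = c("a_inf", "a1", "a2", "tau1_s", "tau2_s"),
    estimate = c(x$a_inf, x$a1, x$a2, x$tau1, x$tau2)
  )
}

#' @describeIn fit_correlation One-row fit summary.
#' @export
glance.corr_fit <- function(x, ...) {
  tibble(ssr = x$ssr, nobs = nrow(x$data), flag = x$flag)
}

#' @describeIn transition_rates Rate estimates as a tibble.
#' @param x A `gate_rates` object.
#' @param ... Unused.
#' @export
tidy.gate_rates <- function(x, ...) {
  tibble(
    direction = c("opening", "closing"),
    k_s = c(x$k_open, x$k_close),
    n_events = c(x$n_opening, x$n_closing),
    time_in_origin_state_s = c(x$time_closed_s, x$time_open_s),
    upper_bound = c(x$k_open_upper_bound, x$k_close_upper_bound)
  )
}

#' @describeIn pmf_from_work Free-energy profile as a tibble.
#' @param x A `pmf_estimate` object.
#' @param ... Unused.
#' @export
tidy.pmf_estimate <- function(x, ...) x$profile

#' @describeIn pmf_from_work One-row summary with the barrier and CI.
#' @export
glance.pmf_estimate <- function(x, ...) {
  tibble(
    barrier_kcal = x$barrier_kcal,
    ci_lo = if (is.null(x$barrier_ci)) NA_real_ else x$barrier_ci[1],
    ci_hi = if (is.null(x$barrier_ci)) NA_real_ else x$barrier_ci[2],
    n_runs = x$n_runs, temperature = x$temperature
  )
}
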