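# ggplot2 autoplot methods for the package's result objects.

#' @describeIn fit_exponential Trace with the fitted exponential overlaid.
#' @param object A fitted object.
#' @export
autoplot.exp_fit <- function(object, ...) {
  df <- dplyr::mutate(object$data, fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity), alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#2166ac") +
    ggplot2::labs(x = "time (s)", y = "intensity",
                  title = sprintf("Exponential %s fit: k = %.3g s^-1",
                                  object$mode, object$rate_s)) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_aminolysis Linearised rate law with the fitted line.
#' @param object A fitted object.
#' @export
autoplot.aminolysis_fit <- function(object, ...) {
  df <- dplyr::mutate(object$data, y = .data$k_obs / .data$lys_neutral)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lys_neutral, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$kcat1, slope = object$kcat2,
                         colour = "#2166ac") +
    ggplot2::labs(x = "[lys0] (M)", y = "k_obs / [lys0] (M^-1 s^-1)",
                  title = "Aminolysis rate law (linearised)") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_kd Per-residue isotherms with the shared-KD fit curves.
#' @param object A fitted object.
#' @export
autoplot.kd_fit <- function(object, ...) {
  dat <- object$data
  curve <- tidyr::expand_grid(
    residue = object$dd_max$residue,
    ligand_total_M = seq(0, max(dat$ligand_total_M), length.out = 100)
  ) |>
    dplyr::left_join(object$dd_max, by = "residue") |>
    dplyr::mutate(
      protein_total_M = mean(dat$protein_total_M),
      dd_ppm = .data$dd_max_ppm *
        fraction_bound(.data$ligand_total_M, .data$protein_total_M, object$kd_M)
    )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$ligand_total_M * 1e6,
                                    y = .data$dd_ppm,
                                    colour = .data$residue)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve) +
    ggplot2::labs(x = "[ligand] total (uM)", y = "combined CSP (ppm)",
                  title = sprintf("1:1 isotherm fit: KD = %.3g uM",
                                  object$kd_M * 1e6)) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_exchange Observed and fitted lineshapes per titration
#'   point.
#' @param object A fitted object.
#' @export
autoplot.exchange_fit <- function(object, ...) {
  ggplot2::ggplot(object$fitted, ggplot2::aes(x = .data$freq_hz)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity),
                        size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#2166ac") +
    ggplot2::facet_wrap(~point, scales = "free_y") +
    ggplot2::labs(x = "frequency (Hz)", y = "intensity",
                  title = sprintf("Two-site exchange fit: koff = %.3g s^-1",
                                  object$koff)) +
    ggplot2::theme_minimal()
}

#' @describeIn digitize_gate Distance trajectory coloured by assigned
#'   state, with the cutoff line.
#' @param object A `gate_states` object.
#' @param ... Unused.
#' @export
autoplot.gate_states <- function(object, ...) {
  ggplot2::ggplot(object$states,
                  ggplot2::aes(x = .data$time_ps / 1e3, y = .data$distance_A,
                               colour = .data$state)) +
    ggplot2::geom_point(size = 0.2, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = object$cutoff, linetype = 2) +
    ggplot2::labs(x = "time (ns)", y = "gate distance (A)",
                  colour = "state") +
    ggplot2::theme_minimal()
}

#' @describeIn pmf_from_work Free-energy profile with mean work overlaid.
#' @param object A `pmf_estimate` object.
#' @export
autoplot.pmf_estimate <- function(object, ...) {
  df <- object$profile |>
    dplyr::mutate(mean_work_shifted =
                    .data$mean_work_kcal - .data$mean_work_kcal[1]) |>
    tidyr::pivot_longer(c("g_kcal", "mean_work_shifted"),
                        names_to = "quantity", values_to = "kcal")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position_A, y = .data$kcal,
                                   colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(g_kcal = "#2166ac", mean_work_shifted = "grey50"),
      labels = c(g_kcal = "cumulant dG(x)", mean_work_shifted = "mean work")) +
    ggplot2::labs(x = "pulling coordinate (A)", y = "kcal/mol",
                  colour = NULL,
                  title = sprintf("Barrier = %.2f kcal/mol", object$barrier_kcal)) +
    ggplot2::theme_minimal()
}
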