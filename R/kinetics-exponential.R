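# Exponential fits for conjugation / hydrolysis / aminolysis traces.

#' Fit a single-exponential kinetic trace
#'
#' Least-squares fit of `offset + amplitude * (1 - exp(-k t))` (rise) or
#' `offset + amplitude * exp(-k t)` (decay) to a time/intensity trace, as
#' used for thioester build-up and loss assays. Starting values come from
#' a log-linear transform; refinement uses Levenberg-Marquardt.
#'
#' @param trace A data frame with columns `time_s` and `intensity` (e.g.
#'   from [sim_exponential_trace()] or [read_kinetic_trace()]).
#' @param mode `"auto"` (detect from the trend), `"rise"` or `"decay"`.
#' @return An object of class `exp_fit`: a list with elements `rate_s`
#'   (k, s^-1), `amplitude`, `offset`, their standard errors (`rate_se`,
#'   `amplitude_se`, `offset_se`), `mode`, `converged`, `flag` (NA or a
#'   diagnostic string), `data` and `fitted`. Supports [tidy()], [glance()]
#'   and [autoplot()]. Rates are in s^-1; see [per_minute()] for min^-1.
#' @examples
#' tr <- sim_exponential_trace(seq(0, 1200, 60), rate = 0.19 / 60)
#' fit <- fit_exponential(tr)
#' per_minute(fit$rate_s) # ~0.19 min^-1
#' @export
fit_exponential <- function(trace, mode = c("auto", "rise", "decay")) {
  mode <- match.arg(mode)
  .require_cols(trace, c("time_s", "intensity"), "`trace`")
  t <- as.numeric(trace$time_s)
  y <- as.numeric(trace$intensity)
  if (length(t) < 4) abort("need at least 4 points for an exponential fit")
  if (is.unsorted(t, strictly = TRUE)) abort("`time_s` must be strictly increasing")

  rng <- diff(range(y))
  if (rng <= .Machine$double.eps * max(1, abs(mean(y)))) {
    return(.exp_fit_flagged(trace, mode, "constant trace: rate unidentifiable"))
  }
  if (mode == "auto") {
    mode <- if (coef(lm(y ~ t))[2] >= 0) "rise" else "decay"
  }

  # crude start: amplitude/offset from extremes, rate from 1/3 of time span
  k0 <- max(1 / (max(t) - min(t)), 1e-12) * 3
  if (mode == "decay") {
    off0 <- min(y); amp0 <- max(y) - off0
  } else {
    off0 <- y[1]; amp0 <- max(y) - y[1]
  }
  model_fun <- function(p, tt) {
    k <- exp(p[1]); a <- p[2]; o <- p[3]
    if (mode == "rise") o + a * (1 - exp(-k * tt)) else o + a * exp(-k * tt)
  }
  best <- NULL
  for (kf in c(0.2, 1, 5, 25)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(log(k0 * kf), amp0, off0),
        fn = function(p) y - model_fun(p, t),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) {
    return(.exp_fit_flagged(trace, mode, "optimizer failed to converge"))
  }

  p <- best$par
  k_hat <- exp(p[1])
  # delta-method SEs from the LM covariance on (log k, amplitude, offset)
  dof <- length(y) - 3
  sigma2 <- best$deviance / max(dof, 1)
  cov <- tryCatch(sigma2 * solve(best$hessian / 2), error = function(e) NULL)
  if (is.null(cov)) {
    ses <- c(NA_real_, NA_real_, NA_real_)
  } else {
    ses <- sqrt(pmax(diag(cov), 0))
    ses[1] <- ses[1] * k_hat # d k / d log k = k
  }
  fitted <- model_fun(p, t)
  structure(list(
    rate_s = k_hat, amplitude = p[2], offset = p[3],
    rate_se = ses[1], amplitude_se = ses[2], offset_se = ses[3],
    mode = mode, converged = best$info %in% 1:4, flag = NA_character_,
    deviance = best$deviance, n = length(y),
    data = as_tibble(trace), fitted = fitted
  ), class = "exp_fit")
}

.exp_fit_flagged <- function(trace, mode, msg) {
  structure(list(
    rate_s = NA_real_, amplitude = 0, offset = mean(trace$intensity),
    rate_se = NA_real_, amplitude_se = NA_real_, offset_se = NA_real_,
    mode = mode, converged = FALSE, flag = msg,
    deviance = NA_real_, n = nrow(trace),
    data = as_tibble(trace), fitted = rep(mean(trace$intensity), nrow(trace))
  ), class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat("Exponential fit (", x$mode, ")\n", sep = "")
  if (!is.na(x$flag)) cat("  FLAGGED:", x$flag, "\n")
  cat(sprintf("  k_obs    = %.6g s^-1 (%.6g min^-1), se %.3g\n",
              x$rate_s, per_minute(x$rate_s), x$rate_se))
  cat(sprintf("  amplitude = %.6g (se %.3g); offset = %.6g (se %.3g)\n",
              x$amplitude, x$amplitude_se, x$offset, x$offset_se))
  invisible(x)
}

#' Convert a per-second rate to per-minute (and back)
#'
#' Internal computations use seconds and molar; assay literature often
#' quotes min^-1. These helpers convert at the I/O boundary.
#'
#' @param k_s Rate in s^-1.
#' @param k_min Rate in min^-1.
#' @return The converted rate.
#' @export
per_minute <- function(k_s) k_s * 60

#' @rdname per_minute
#' @export
per_second <- function(k_min) k_min / 60

#' Apparent conjugation rate constant
#'
#' Normalises an observed thioester build-up rate by the E1 concentration:
#' `k_app = k_obs / [E1]`, enabling comparison across enzyme variants
#' assayed at the same E2 concentration.
#'
#' @param k_obs Observed rate, s^-1 (or min^-1; the output carries the same
#'   time unit).
#' @param e1_conc E1 concentration in molar (> 0).
#' @return Apparent second-order rate constant, M^-1 per input time unit.
#' @examples
#' apparent_rate(per_second(0.594), 330e-9) * 60 # ~1.8e6 M^-1 min^-1
#' @export
apparent_rate <- function(k_obs, e1_conc) {
  if (any(e1_conc <= 0)) abort("`e1_conc` must be > 0")
  k_obs / e1_conc
}
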