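# Back-calculation of 15N R1/R2/NOE from correlation-function models,
# five-parameter correlation fits, tau_c from the R2/R1 ratio, and
# open/closed population weighting.
#
# Conventions: the internal correlation function is normalised to
# C_int(0) = 1 (plateau + two exponentials, amplitudes summing to 1); the
# 2/5 factor of the isotropic-tumbling correlation function lives in the
# spectral density J(omega), not in C_int.

#' Physical constants for 15N relaxation back-calculation
#'
#' @param r_nh N-H bond length in metres (default 1.02 Angstrom).
#' @param csa_ppm 15N chemical shift anisotropy in ppm (default -172).
#' @return A list with the dipolar coupling `d` (rad/s) factory and
#'   gyromagnetic ratios, used internally by [calc_relaxation()].
#' @keywords internal
.relax_constants <- function(r_nh = 1.02e-10, csa_ppm = -172) {
  d <- .const$mu0_4pi * .const$gamma_h * abs(.const$gamma_n) * .const$hbar / r_nh^3
  list(d = d, csa = csa_ppm * 1e-6,
       gamma_h = .const$gamma_h, gamma_n = .const$gamma_n)
}

#' Construct a correlation-function model
#'
#' Internal amide-vector correlation function
#' `C(t) = a_inf + a1 * exp(-t/tau1) + a2 * exp(-t/tau2)` with
#' `a_inf + a1 + a2 = 1`. The plateau `a_inf` plays the role of a
#' generalised order parameter; the two exponentials capture fast and slow
#' internal motions.
#'
#' @param a_inf Plateau amplitude in `[0, 1]`.
#' @param a1,a2 Amplitudes of the internal decays (each in `[0, 1]`).
#' @param tau1,tau2 Internal correlation times, seconds (ignored when the
#'   matching amplitude is 0).
#' @param tol Tolerance on the amplitude sum.
#' @return An object of class `correlation_model`.
#' @examples
#' rigid <- correlation_model(1)                      # rigid limit
#' flex  <- correlation_model(0.8, 0.2, tau1 = 100e-12)
#' @export
correlation_model <- function(a_inf, a1 = 0, a2 = 0,
                              tau1 = NULL, tau2 = NULL, tol = 1e-6) {
  amps <- c(a_inf, a1, a2)
  if (any(amps < -tol) || any(amps > 1 + tol)) {
    abort("amplitudes must lie in [0, 1]")
  }
  if (abs(sum(amps) - 1) > tol) abort("amplitudes must sum to 1")
  if (a1 > 0 && (is.null(tau1) || tau1 <= 0)) abort("tau1 must be > 0 when a1 > 0")
  if (a2 > 0 && (is.null(tau2) || tau2 <= 0)) abort("tau2 must be > 0 when a2 > 0")
  structure(list(a_inf = a_inf, a1 = a1, a2 = a2,
                 tau1 = tau1 %||% Inf, tau2 = tau2 %||% Inf),
            class = "correlation_model")
}

#' Evaluate the internal correlation function of a model
#'
#' @param model A [correlation_model()].
#' @param t Lag times, seconds.
#' @return `C(t)` values.
#' @export
correlation_function <- function(model, t) {
  stopifnot(inherits(model, "correlation_model"))
  model$a_inf + model$a1 * exp(-t / model$tau1) + model$a2 * exp(-t / model$tau2)
}

#' Fit a five-parameter correlation decay
#'
#' Least-squares fit of `C(t) = a_inf + a1 exp(-t/tau1) + a2 exp(-t/tau2)`
#' to a sampled amide-vector autocorrelation (e.g. from 20-ns MD windows),
#' with amplitudes constrained to `[0, 1]` and to sum to one
#' (`a2 = 1 - a_inf - a1`). Starting points for the two time scales come
#' from a small multi-start grid spanning the lag range; refinement is
#' Levenberg-Marquardt.
#'
#' @param corr A data frame with columns `lag_s` and `c` (`c[1]` should be
#'   1 within tolerance).
#' @return An object of class `corr_fit`: the fitted [correlation_model()]
#'   plus `flag`, `ssr`, `data`, `fitted`. Supports [tidy()] and
#'   [glance()].
#' @export
fit_correlation <- function(corr) {
  .require_cols(corr, c("lag_s", "c"), "`corr`")
  t <- as.numeric(corr$lag_s)
  y <- as.numeric(corr$c)
  if (length(t) < 6) abort("need at least 6 lag points")
  if (abs(y[which.min(t)] - 1) > 0.05) {
    warn("C(0) differs from 1 by more than 5%; fit assumes unit normalisation")
  }
  flag <- NA_character_
  if (y[which.max(t)] > 0.999 && diff(range(y)) < 1e-3) {
    # rigid limit: nothing decays
    m <- correlation_model(1)
    return(structure(c(unclass(m), list(flag = "non-decaying input (rigid limit)",
                                        ssr = sum((y - 1)^2),
                                        data = as_tibble(corr),
                                        fitted = rep(1, length(t)))),
                     class = c("corr_fit", "correlation_model")))
  }

  tmax <- max(t[t > 0])
  model_fun <- function(p, tt) {
    a_inf <- p[1]; a1 <- p[2]
    a2 <- 1 - a_inf - a1
    a_inf + a1 * exp(-tt / exp(p[3])) + a2 * exp(-tt / exp(p[4]))
  }
  resid_fun <- function(p) {
    a2 <- 1 - p[1] - p[2]
    pen <- 1e3 * (max(0, -a2) + max(0, a2 - 1))
    c(y - model_fun(p, t), pen)
  }
  starts <- tidyr::expand_grid(tau1 = tmax * c(0.002, 0.02),
                               tau2 = tmax * c(0.2, 1))
  best <- NULL
  a_inf0 <- max(min(y[which.max(t)], 1), 0)
  a10 <- (1 - a_inf0) / 2
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(a_inf0, a10, log(starts$tau1[i]), log(starts$tau2[i])),
        fn = resid_fun,
        lower = c(0, 0, log(tmax * 1e-6), log(tmax * 1e-6)),
        upper = c(1, 1, log(tmax * 1e3), log(tmax * 1e3)),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) abort("correlation fit failed to converge")
  p <- best$par
  tau <- sort(exp(p[3:4]))
  # order so tau1 <= tau2
  if (exp(p[3]) > exp(p[4])) {
    p <- c(p[1], 1 - p[1] - p[2], p[4], p[3])
  }
  a2 <- max(1 - p[1] - p[2], 0)
  m <- correlation_model(min(max(p[1], 0), 1), min(max(p[2], 0), 1), a2,
                         tau1 = exp(p[3]), tau2 = exp(p[4]), tol = 1e-3)
  structure(c(unclass(m), list(flag = flag, ssr = best$deviance,
                               data = as_tibble(corr),
                               fitted = model_fun(p, t))),
            class = c("corr_fit", "correlation_model"))
}

#' Spectral density of a correlation model under isotropic tumbling
#'
#' `J(w) = (2/5) [a_inf tc/(1+(w tc)^2) + sum_i a_i ti'/(1+(w ti')^2)]`
#' with `1/ti' = 1/tc + 1/tau_i`: the Fourier transform of the internal
#' correlation function multiplied by the overall tumbling decay
#' `exp(-t/tc)`. The 2/5 normalisation lives here so that the internal
#' correlation function is unit-normalised.
#'
#' @param model A [correlation_model()].
#' @param omega Angular frequencies, rad/s (vectorised).
#' @param tauc Overall rotational correlation time, seconds.
#' @return `J(omega)` in s/rad.
#' @export
spectral_density <- function(model, omega, tauc) {
  stopifnot(inherits(model, "correlation_model"), tauc > 0)
  lor <- function(a, tau) {
    if (a == 0) return(0 * omega)
    teff <- 1 / (1 / tauc + 1 / tau)
    a * teff / (1 + (omega * teff)^2)
  }
  (2 / 5) * (model$a_inf * tauc / (1 + (omega * tauc)^2) +
               lor(model$a1, model$tau1) + lor(model$a2, model$tau2))
}

#' Back-calculate 15N relaxation rates from a correlation model
#'
#' Standard dipolar + CSA expressions for amide 15N relaxation:
#' \deqn{R1 = (d^2/4)[J(wH-wN) + 3J(wN) + 6J(wH+wN)] + c^2 J(wN)}
#' \deqn{R2 = (d^2/8)[4J(0) + J(wH-wN) + 3J(wN) + 6J(wH) + 6J(wH+wN)] +
#'   (c^2/6)[4J(0) + 3J(wN)]}
#' \deqn{NOE = 1 + (gH/gN)(d^2/4)[6J(wH+wN) - J(wH-wN)]/R1}
#' with `d` the dipolar coupling constant and `c = wN * CSA / sqrt(3)`.
#'
#' @param model A [correlation_model()].
#' @param tauc Overall correlation time, seconds.
#' @param field_mhz 1H spectrometer frequency, MHz (default 600).
#' @param r_nh N-H bond length, metres.
#' @param csa_ppm 15N CSA, ppm.
#' @return A tibble with columns `r1_s`, `r2_s`, `noe`, `field_mhz`,
#'   `tauc_s`.
#' @export
calc_relaxation <- function(model, tauc, field_mhz = 600,
                            r_nh = 1.02e-10, csa_ppm = -172) {
  k <- .relax_constants(r_nh, csa_ppm)
  wh <- 2 * pi * field_mhz * 1e6
  wn <- wh * k$gamma_n / k$gamma_h # signed
  J <- function(w) spectral_density(model, w, tauc)
  d2 <- k$d^2
  c2 <- (wn * k$csa / sqrt(3))^2
  r1 <- d2 / 4 * (J(wh - wn) + 3 * J(wn) + 6 * J(wh + wn)) + c2 * J(wn)
  r2 <- d2 / 8 * (4 * J(0) + J(wh - wn) + 3 * J(wn) + 6 * J(wh) +
                    6 * J(wh + wn)) + c2 / 6 * (4 * J(0) + 3 * J(wn))
  noe <- 1 + (k$gamma_h / k$gamma_n) * (d2 / 4) *
    (6 * J(wh + wn) - J(wh - wn)) / r1
  tibble(r1_s = r1, r2_s = r2, noe = noe, field_mhz = field_mhz, tauc_s = tauc)
}

#' Overall correlation time from the R2/R1 ratio
#'
#' For rigid residues the R2/R1 ratio is a monotone function of the overall
#' tumbling time, so each residue's `tauc` is found by root bisection of
#' the rigid-rotor (plateau-only) back-calculation. Residues whose ratio
#' falls outside the attainable rigid-rotor range are excluded (with a
#' message); a trimmed mean over the remaining residues is returned to
#' mimic the exclusion of flexible or exchange-broadened sites.
#'
#' @param records A data frame with columns `residue`, `r1_s`, `r2_s`.
#' @param field_mhz 1H spectrometer frequency, MHz.
#' @param trim Trim fraction for the mean (default 0.1).
#' @param tauc_bounds Search interval in seconds.
#' @param r_nh,csa_ppm Physical constants, as in [calc_relaxation()].
#' @return A list with `tauc_s` (trimmed mean), `per_residue` (tibble of
#'   residue-level estimates), `excluded` (residues outside range).
#' @export
tauc_from_r2r1 <- function(records, field_mhz = 600, trim = 0.1,
                           tauc_bounds = c(0.5e-9, 100e-9),
                           r_nh = 1.02e-10, csa_ppm = -172) {
  .require_cols(records, c("residue", "r1_s", "r2_s"), "`records`")
  rigid <- correlation_model(1)
  ratio_at <- function(tc) {
    r <- calc_relaxation(rigid, tc, field_mhz, r_nh, csa_ppm)
    r$r2_s / r$r1_s
  }
  lo <- ratio_at(tauc_bounds[1]); hi <- ratio_at(tauc_bounds[2])
  res <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    ratio <- records$r2_s[i] / records$r1_s[i]
    if (!is.finite(ratio) || ratio < lo || ratio > hi) {
      return(tibble(residue = records$residue[i], tauc_s = NA_real_))
    }
    root <- uniroot(function(tc) ratio_at(tc) - ratio, tauc_bounds,
                    tol = 1e-15)
    tibble(residue = records$residue[i], tauc_s = root$root)
  })
  excluded <- res$residue[is.na(res$tauc_s)]
  if (length(excluded) > 0) {
    message("excluded ", length(excluded),
            " residue(s) with R2/R1 outside the rigid-rotor range: ",
            paste(excluded, collapse = ", "))
  }
  keep <- res$tauc_s[!is.na(res$tauc_s)]
  if (length(keep) == 0) abort("no residues with attainable R2/R1 ratios")
  list(tauc_s = mean(keep, trim = trim), per_residue = res,
       excluded = excluded)
}

#' Population-weighted combination of open/closed relaxation rates
#'
#' Combines back-calculated rates for the open and closed gate states by
#' the state populations: `R1` and `R2` as convex combinations, and the
#' NOE via the underlying cross-relaxation rate
#' `sigma = (NOE - 1) R1 gN/gH` (weighting the ratio itself would be
#' incorrect because the NOE is a quotient of rates).
#'
#' @param open,closed Tibbles as returned by [calc_relaxation()] (same
#'   field).
#' @param fraction_open Open-state population in `[0, 1]`.
#' @return A tibble with the combined `r1_s`, `r2_s`, `noe`, `field_mhz`.
#' @export
population_weighted_rates <- function(open, closed, fraction_open) {
  .require_cols(open, c("r1_s", "r2_s", "noe", "field_mhz"), "`open`")
  .require_cols(closed, c("r1_s", "r2_s", "noe", "field_mhz"), "`closed`")
  if (fraction_open < 0 || fraction_open > 1) {
    abort("`fraction_open` must be in [0, 1]")
  }
  if (nrow(open) != nrow(closed) ||
      any(open$field_mhz != closed$field_mhz)) {
    abort("`open` and `closed` must match row-for-row at the same field")
  }
  w <- fraction_open
  g <- .const$gamma_n / .const$gamma_h
  sig_o <- (open$noe - 1) * open$r1_s * g
  sig_c <- (closed$noe - 1) * closed$r1_s * g
  r1 <- w * open$r1_s + (1 - w) * closed$r1_s
  sig <- w * sig_o + (1 - w) * sig_c
  tibble(
    r1_s = r1,
    r2_s = w * open$r2_s + (1 - w) * closed$r2_s,
    noe = 1 + sig / (g * r1),
    field_mhz = open$field_mhz
  )
}
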