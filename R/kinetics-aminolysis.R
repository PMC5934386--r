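# Quadratic neutral-lysine aminolysis rate law and the side-chain ASA trend.

#' Neutral-side-chain lysine concentration
#'
#' Henderson-Hasselbalch fraction of total lysine with a neutral
#' (deprotonated) side-chain amine:
#' `[lys0] = lys_total / (1 + 10^(pKa - pH))`.
#'
#' @param lys_total Total lysine concentration, molar.
#' @param pH Solution pH.
#' @param pKa Lysine side-chain pKa (default 10.54).
#' @return Neutral lysine concentration, molar.
#' @examples
#' neutral_lysine(30e-3, pH = 8.0) # ~8.63e-5 M
#' @export
neutral_lysine <- function(lys_total, pH = 8.0, pKa = 10.54) {
  if (any(lys_total < 0)) abort("`lys_total` must be >= 0")
  lys_total / (1 + 10^(pKa - pH))
}

#' Fit the quadratic aminolysis rate law
#'
#' Observed aminolysis rates are quadratic in the neutral-lysine
#' concentration: `k_obs = kcat1 * [lys0] + kcat2 * [lys0]^2`. Dividing by
#' `[lys0]` linearises the law, so `k_obs/[lys0]` regressed on `[lys0]`
#' yields `kcat1` as intercept and `kcat2` as slope (weighted least
#' squares).
#'
#' @param series A data frame with columns `lys_total` (M) and `k_obs`
#'   (s^-1), e.g. from [sim_aminolysis_rates()].
#' @param pH,pKa Passed to [neutral_lysine()].
#' @param weights Optional regression weights (default uniform).
#' @return An object of class `aminolysis_fit` with elements `kcat1`
#'   (M^-1 s^-1), `kcat2` (M^-2 s^-1), `kcat1_se`, `kcat2_se`, `r_squared`,
#'   `pH`, `pKa`, `data` and the underlying `lm` fit. Supports [tidy()] and
#'   [glance()].
#' @export
fit_aminolysis <- function(series, pH = 8.0, pKa = 10.54, weights = NULL) {
  .require_cols(series, c("lys_total", "k_obs"), "`series`")
  if (length(unique(series$lys_total)) < 3) {
    abort("need >= 3 distinct lysine concentrations")
  }
  if (any(series$lys_total <= 0)) abort("lysine concentrations must be > 0")
  lys0 <- neutral_lysine(series$lys_total, pH = pH, pKa = pKa)
  yy <- series$k_obs / lys0
  df <- tibble(lys0 = lys0, y = yy)
  w <- weights %||% rep(1, nrow(df))
  fit <- lm(y ~ lys0, data = df, weights = w)
  # noiseless synthetic data legitimately yields a perfect fit
  sm <- suppressWarnings(summary(fit))
  structure(list(
    kcat1 = unname(coef(fit)[1]), kcat2 = unname(coef(fit)[2]),
    kcat1_se = sm$coefficients[1, 2], kcat2_se = sm$coefficients[2, 2],
    r_squared = sm$r.squared, pH = pH, pKa = pKa,
    data = dplyr::mutate(as_tibble(series), lys_neutral = lys0),
    lm_fit = fit
  ), class = "aminolysis_fit")
}

#' @export
print.aminolysis_fit <- function(x, ...) {
  cat("Aminolysis rate-law fit (pH", x$pH, ", pKa", x$pKa, ")\n")
  cat(sprintf("  kcat1 = %.4g +/- %.3g M^-1 s^-1\n", x$kcat1, x$kcat1_se))
  cat(sprintf("  kcat2 = %.4g +/- %.3g M^-2 s^-1  (R^2 = %.4f)\n",
              x$kcat2, x$kcat2_se, x$r_squared))
  invisible(x)
}

#' Theoretical maximum residue solvent accessibilities
#'
#' The theoretical maximum accessible surface area scale of Tien et al.
#' (2013), in square Angstrom per residue, used as the default x-axis for
#' rate-versus-ASA regressions. Any other scale can be supplied instead.
#'
#' @return A named numeric vector (one-letter residue codes).
#' @export
asa_scale <- function() {
  c(A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223,
    G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
    P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174)
}

#' Regress catalytic rates on side-chain accessible surface area
#'
#' Ordinary least squares of per-variant rate constants on the accessible
#' surface area of the substituted side chain, quantifying the
#' hydrophobic-surface trend seen for active-site gate substitutions.
#'
#' @param rates A data frame with columns `residue` (one-letter code of the
#'   substituted side chain) and `rate`.
#' @param asa Named numeric ASA table; defaults to [asa_scale()].
#' @return A tibble with columns `slope`, `intercept`, `r_squared`,
#'   `slope_se`, `n`.
#' @export
fit_rate_vs_asa <- function(rates, asa = asa_scale()) {
  .require_cols(rates, c("residue", "rate"), "`rates`")
  if (nrow(rates) < 3) abort("need >= 3 variants")
  missing <- setdiff(rates$residue, names(asa))
  if (length(missing) > 0) {
    abort(paste0("residue(s) absent from ASA table: ",
                 paste(missing, collapse = ", ")))
  }
  x <- asa[rates$residue]
  fit <- lm(rates$rate ~ x)
  sm <- suppressWarnings(summary(fit))
  tibble(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared, slope_se = sm$coefficients[2, 2],
    n = nrow(rates)
  )
}
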