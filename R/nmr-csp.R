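# Chemical shift perturbation analysis and 1:1 binding-isotherm fitting
# with explicit ligand depletion.

#' Combined amide chemical shift perturbation
#'
#' Combines proton and nitrogen amide shift changes into a single CSP:
#' `sqrt((d1H)^2 + (d15N/5)^2)`, the conventional 1/5 nitrogen scaling.
#'
#' @param dd_hn 1HN shift change, ppm.
#' @param dd_n 15N shift change, ppm.
#' @return Combined CSP, ppm (vectorised).
#' @examples
#' csp(0, 0.5) # 0.1
#' @export
csp <- function(dd_hn, dd_n) {
  sqrt(dd_hn^2 + (dd_n / 5)^2)
}

#' Select residues with significant shift perturbations
#'
#' Flags residues whose CSP exceeds the mean plus one standard deviation of
#' all supplied CSPs — the conventional significance rule for mapping a
#' binding interface.
#'
#' @param records A data frame with columns `residue` and `dd_ppm`.
#' @param n_sigma Number of standard deviations above the mean (default 1).
#' @return The subset tibble of significant records, with the threshold in
#'   attribute `"threshold"`.
#' @export
significant_csps <- function(records, n_sigma = 1) {
  .require_cols(records, c("residue", "dd_ppm"), "`records`")
  if (nrow(records) < 2) abort("need at least two residues")
  thr <- mean(records$dd_ppm) + n_sigma * sd(records$dd_ppm)
  out <- dplyr::filter(as_tibble(records), .data$dd_ppm > thr)
  attr(out, "threshold") <- thr
  out
}

#' Free ligand and bound fraction under 1:1 depletion
#'
#' Exact quadratic mass balance for 1:1 binding: the complex concentration
#' is the smaller root of `C^2 - (P + L + KD) C + P L = 0`, giving
#' free ligand `L - C` and bound protein fraction `C / P`.
#'
#' @param ligand_total,protein_total Total concentrations, molar.
#' @param kd Dissociation constant, molar.
#' @return For [free_ligand()], free ligand concentration (M); for
#'   [fraction_bound()], the bound protein fraction in `[0, 1]`.
#' @export
free_ligand <- function(ligand_total, protein_total, kd) {
  b <- protein_total + ligand_total + kd
  complex <- (b - sqrt(b^2 - 4 * protein_total * ligand_total)) / 2
  pmax(ligand_total - complex, 0)
}

#' @rdname free_ligand
#' @export
fraction_bound <- function(ligand_total, protein_total, kd) {
  n <- max(length(ligand_total), length(protein_total))
  lt <- rep_len(ligand_total, n)
  pt <- rep_len(protein_total, n)
  b <- pt + lt + kd
  complex <- (b - sqrt(b^2 - 4 * pt * lt)) / 2
  out <- numeric(n)
  pos <- pt > 0
  out[pos] <- complex[pos] / pt[pos]
  out
}

#' Fit a 1:1 binding isotherm to a CSP titration
#'
#' Fits `dd = dd_max * fraction_bound(L, P, KD)` with the bound fraction
#' from the exact depletion mass balance at each titration point. The
#' default mode fits one global `KD` shared across residues with
#' per-residue `dd_max` (solved in closed form at each candidate `KD`, so
#' the search is one-dimensional). The `"per_residue"` mode instead fits
#' each residue separately and reports the average `KD`.
#'
#' @param titration A data frame with columns `residue`, `ligand_total_M`,
#'   `protein_total_M`, `dd_ppm` (e.g. from [sim_csp_titration()]).
#' @param residues Optional subset of residues to fit (e.g. the output of
#'   [significant_csps()]); default all.
#' @param mode `"global"` (shared KD) or `"per_residue"` (average of
#'   independent KDs).
#' @param kd_bounds Search interval for KD, molar.
#' @return An object of class `kd_fit` with elements `kd_M`, `kd_se_M`,
#'   `dd_max` (per-residue tibble), `mode`, `flag` (NA or a saturation
#'   warning), `per_residue` (individual KDs in per-residue mode), `data`.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_kd <- function(titration, residues = NULL,
                   mode = c("global", "per_residue"),
                   kd_bounds = c(1e-7, 1e-1)) {
  mode <- match.arg(mode)
  .require_cols(titration, c("residue", "ligand_total_M", "protein_total_M",
                             "dd_ppm"), "`titration`")
  dat <- as_tibble(titration)
  if (!is.null(residues)) {
    if (is.data.frame(residues)) residues <- unique(residues$residue)
    dat <- dplyr::filter(dat, .data$residue %in% residues)
  }
  nonzero <- dplyr::filter(dat, .data$ligand_total_M > 0)
  if (length(unique(nonzero$ligand_total_M)) < 3) {
    abort("need >= 3 nonzero ligand points")
  }

  # closed-form per-residue dd_max given KD, and the resulting SSR
  ssr_at <- function(log_kd, d) {
    kd <- exp(log_kd)
    d |>
      dplyr::mutate(fb = fraction_bound(.data$ligand_total_M,
                                        .data$protein_total_M, kd)) |>
      dplyr::group_by(.data$residue) |>
      dplyr::summarise(
        ssr = {
          ddm <- sum(.data$fb * .data$dd_ppm) / max(sum(.data$fb^2), 1e-300)
          sum((.data$dd_ppm - ddm * .data$fb)^2)
        }, .groups = "drop") |>
      dplyr::pull(.data$ssr) |>
      sum()
  }
  fit_one <- function(d) {
    opt <- optimize(ssr_at, log(kd_bounds), d = d, tol = 1e-12)
    kd <- exp(opt$minimum)
    # curvature of SSR in KD for a delta-method standard error
    h <- kd * 1e-3
    d2 <- (ssr_at(log(kd + h), d) - 2 * opt$objective +
             ssr_at(log(max(kd - h, kd_bounds[1] / 10)), d)) / (h / kd)^2
    dof <- max(nrow(d) - length(unique(d$residue)) - 1, 1)
    sigma2 <- opt$objective / dof
    se_log <- if (is.finite(d2) && d2 > 0) sqrt(2 * sigma2 / d2) else Inf
    list(kd = kd, se = se_log * kd, ssr = opt$objective)
  }

  if (mode == "global") {
    res <- fit_one(dat)
    kd_hat <- res$kd; kd_se <- res$se; per_res <- NULL; ssr <- res$ssr
  } else {
    per_res <- dat |>
      dplyr::group_split(.data$residue) |>
      purrr::map_dfr(function(d) {
        r <- fit_one(d)
        tibble(residue = d$residue[1], kd_M = r$kd, kd_se_M = r$se)
      })
    kd_hat <- mean(per_res$kd_M)
    kd_se <- sd(per_res$kd_M) / sqrt(nrow(per_res))
    ssr <- NA_real_
  }

  dd_max <- dat |>
    dplyr::mutate(fb = fraction_bound(.data$ligand_total_M,
                                      .data$protein_total_M, kd_hat)) |>
    dplyr::group_by(.data$residue) |>
    dplyr::summarise(
      dd_max_ppm = sum(.data$fb * .data$dd_ppm) / max(sum(.data$fb^2), 1e-300),
      .groups = "drop")

  top_sat <- max(fraction_bound(dat$ligand_total_M, dat$protein_total_M, kd_hat))
  flag <- if (top_sat < 0.5) {
    sprintf("saturation only %.0f%% at top point: KD poorly determined",
            100 * top_sat)
  } else NA_character_

  structure(list(
    kd_M = kd_hat, kd_se_M = kd_se, dd_max = dd_max, mode = mode,
    flag = flag, per_residue = per_res, ssr = ssr, data = dat
  ), class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat("1:1 binding isotherm fit (", x$mode, " mode)\n", sep = "")
  if (!is.na(x$flag)) cat("  FLAGGED:", x$flag, "\n")
  cat(sprintf("  KD = %.4g uM (se %.3g uM), %d residue(s)\n",
              x$kd_M * 1e6, x$kd_se_M * 1e6, nrow(x$dd_max)))
  invisible(x)
}
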