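# Free-energy profiles from steered-work ensembles via the second-order
# Jarzynski cumulant expansion.

#' Free-energy profile from a steered-work ensemble
#'
#' Second-order cumulant expansion of the Jarzynski equality:
#' `dG(x) = <W(x)> - (beta/2) Var(W(x))` with `beta = 1/RT`, evaluated on a
#' common position grid (runs on different grids are resampled by linear
#' interpolation). The profile is shifted so `dG` at the first position is
#' zero; the barrier is the profile maximum. A seeded bootstrap over runs
#' provides a confidence interval on the barrier.
#'
#' @param ensemble A data frame with columns `position_A`, `run`,
#'   `work_kcal` (e.g. from [sim_work_ensemble()] or
#'   [read_work_ensemble()]).
#' @param temperature Temperature, kelvin.
#' @param n_boot Number of bootstrap resamples (default 1000; 0 disables).
#' @param seed Seed for the bootstrap resampling.
#' @param conf Confidence level for the bootstrap interval.
#' @return An object of class `pmf_estimate`: list with `profile` (tibble
#'   `position_A`, `g_kcal`, `mean_work_kcal`, `var_work_kcal2`),
#'   `barrier_kcal`, `barrier_ci` (length-2 numeric or NULL), `n_runs`,
#'   `temperature`. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' pmf <- pmf_gaussian_barrier(barrier = 6.1)
#' w <- sim_work_ensemble(pmf, sigma_w = 1, n_runs = 150, seed = 7)
#' fit <- pmf_from_work(w, seed = 7)
#' @export
pmf_from_work <- function(ensemble, temperature = 298, n_boot = 1000,
                          seed = NULL, conf = 0.95) {
  .require_cols(ensemble, c("position_A", "run", "work_kcal"), "`ensemble`")
  runs <- split(ensemble, ensemble$run)
  if (length(runs) < 2) abort("need at least 2 runs")

  # common grid: overlap of all runs, resolution of the first
  lo <- max(vapply(runs, function(d) min(d$position_A), numeric(1)))
  hi <- min(vapply(runs, function(d) max(d$position_A), numeric(1)))
  if (lo >= hi) abort("runs have non-overlapping position ranges")
  g1 <- sort(unique(runs[[1]]$position_A))
  grid <- g1[g1 >= lo & g1 <= hi]
  if (length(grid) < 2) abort("fewer than two common grid positions")

  W <- vapply(runs, function(d) {
    d <- dplyr::arrange(d, .data$position_A)
    if (is.unsorted(d$position_A, strictly = TRUE)) {
      abort("positions within a run must be strictly monotone")
    }
    approx(d$position_A, d$work_kcal, xout = grid)$y
  }, numeric(length(grid)))          # positions x runs

  beta <- 1 / .rt_kcal(temperature)
  est_profile <- function(mat) {
    mw <- rowMeans(mat)
    vw <- apply(mat, 1, var)
    g <- mw - beta / 2 * vw
    g - g[1]
  }
  g <- est_profile(W)
  barrier <- max(g)

  ci <- NULL
  if (n_boot > 0) {
    n <- ncol(W)
    bars <- .with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        max(est_profile(W[, idx, drop = FALSE]))
      }, numeric(1))
    })
    alpha <- (1 - conf) / 2
    ci <- unname(quantile(bars, c(alpha, 1 - alpha)))
  }

  mw <- rowMeans(W); vw <- apply(W, 1, var)
  structure(list(
    profile = tibble(position_A = grid, g_kcal = g,
                     mean_work_kcal = mw, var_work_kcal2 = vw),
    barrier_kcal = barrier, barrier_ci = ci,
    n_runs = length(runs), temperature = temperature
  ), class = "pmf_estimate")
}

#' @export
print.pmf_estimate <- function(x, ...) {
  cat(sprintf("Cumulant-expansion free-energy profile (%d runs, T = %g K)\n",
              x$n_runs, x$temperature))
  cat(sprintf("  barrier = %.3f kcal/mol", x$barrier_kcal))
  if (!is.null(x$barrier_ci)) {
    cat(sprintf("  [%.3f, %.3f] bootstrap CI", x$barrier_ci[1], x$barrier_ci[2]))
  }
  cat("\n")
  invisible(x)
}
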