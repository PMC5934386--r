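# Two-state digitisation of gate distance trajectories, transition-count
# rate estimation, and Eyring conversion between rates and free-energy
# barriers.

#' Digitise a gate distance trajectory into open/closed states
#'
#' Frame-wise thresholding at `cutoff` (distances above the cutoff are
#' "open"), optionally followed by merging of segments shorter than
#' `min_dwell` frames into the flanking state when both neighbours agree.
#' The default `min_dwell = 1` is plain thresholding; a small `min_dwell`
#' suppresses spurious recrossings caused by within-state distance noise
#' near the cutoff.
#'
#' @param traj A data frame with columns `time_ps` and `distance_A` (e.g.
#'   from [sim_gate_trajectory()] or [read_gate_trajectory()]).
#' @param cutoff Open/closed threshold distance, Angstrom (default 12).
#' @param min_dwell Minimum segment length in frames.
#' @return An object of class `gate_states`: a list with `states` (tibble
#'   `time_ps`, `distance_A`, `state`), `dwells` (tibble `state`,
#'   `n_frames`, `duration_s`), `cutoff`, `dt_s`. Supports [autoplot()].
#' @examples
#' seqd <- tibble::tibble(time_ps = 0:4 * 100,
#'                        distance_A = c(8, 13, 5, 14, 11))
#' digitize_gate(seqd)$states$state
#' @export
digitize_gate <- function(traj, cutoff = 12, min_dwell = 1) {
  .require_cols(traj, c("time_ps", "distance_A"), "`traj`")
  if (nrow(traj) < 1) abort("empty trajectory")
  dts <- diff(traj$time_ps)
  if (length(dts) == 0) abort("trajectory must have at least two frames")
  if ((max(dts) - min(dts)) > 1e-6 * stats::median(dts)) {
    abort("trajectory must have a uniform time step")
  }
  dt_s <- stats::median(dts) * 1e-12
  st <- ifelse(traj$distance_A > cutoff, "open", "closed")

  if (min_dwell > 1) {
    # A short interior segment in a binary sequence is always flanked by the
    # opposite state on both sides, so merging means flipping its state.
    # Flip, per pass, every short interior segment whose neighbours are both
    # long (no cascade ambiguity); if only short-neighboured ones remain,
    # flip the single shortest and continue.
    r <- rle(st)
    len <- r$lengths
    val <- r$values
    repeat {
      nseg <- length(len)
      if (nseg < 3) break
      is_short <- len < min_dwell
      cand <- which(is_short)
      cand <- cand[cand > 1 & cand < nseg]
      if (length(cand) == 0) break
      safe <- cand[!is_short[cand - 1] & !is_short[cand + 1]]
      flip <- if (length(safe) > 0) safe else cand[which.min(len[cand])]
      val[flip] <- ifelse(val[flip] == "open", "closed", "open")
      grp <- cumsum(c(TRUE, val[-1] != val[-nseg]))
      len <- as.vector(rowsum(len, grp))
      val <- val[!duplicated(grp)]
    }
    st <- inverse.rle(structure(list(lengths = len, values = val),
                                class = "rle"))
  }
  r <- rle(st)
  dwells <- tibble(state = r$values, n_frames = r$lengths,
                   duration_s = r$lengths * dt_s)
  structure(list(
    states = tibble(time_ps = traj$time_ps, distance_A = traj$distance_A,
                    state = st),
    dwells = dwells, cutoff = cutoff, dt_s = dt_s
  ), class = "gate_states")
}

#' @export
print.gate_states <- function(x, ...) {
  n <- nrow(x$states)
  occ <- mean(x$states$state == "open")
  cat(sprintf("Gate state sequence: %d frames (dt %.3g ps), cutoff %.3g A\n",
              n, x$dt_s * 1e12, x$cutoff))
  cat(sprintf("  %d dwell segments; open occupancy %.3f\n",
              nrow(x$dwells), occ))
  invisible(x)
}

#' Opening and closing rates from transition counts
#'
#' Estimates `k_open` as the number of closed-to-open transitions divided
#' by the total time spent closed, and symmetrically for `k_close`. A
#' state with no exits yields a one-sided upper bound `k < 1/time` (flagged
#' via `upper_bound`), never a failure: long trajectories in which a
#' transition is never observed still carry rate information.
#'
#' @param seq A `gate_states` object from [digitize_gate()].
#' @return An object of class `gate_rates`: list with `k_open`, `k_close`
#'   (s^-1), `n_opening`, `n_closing`, `time_closed_s`, `time_open_s`,
#'   `k_open_upper_bound`, `k_close_upper_bound` (logical). Supports
#'   [tidy()].
#' @export
transition_rates <- function(seq) {
  stopifnot(inherits(seq, "gate_states"))
  if (nrow(seq$states) < 2) abort("need at least two frames")
  d <- seq$dwells
  t_closed <- sum(d$duration_s[d$state == "closed"])
  t_open <- sum(d$duration_s[d$state == "open"])
  # transitions out of each state = segments of that state not at the very end
  n_seg <- nrow(d)
  exits <- d$state[-n_seg]
  n_opening <- sum(exits == "closed")
  n_closing <- sum(exits == "open")

  one <- function(n, t_state, t_total) {
    if (t_state <= 0) return(list(k = NA_real_, ub = FALSE))
    if (n == 0) list(k = 1 / t_state, ub = TRUE) else list(k = n / t_state, ub = FALSE)
  }
  ko <- one(n_opening, t_closed)
  kc <- one(n_closing, t_open)
  structure(list(
    k_open = ko$k, k_close = kc$k,
    n_opening = n_opening, n_closing = n_closing,
    time_closed_s = t_closed, time_open_s = t_open,
    k_open_upper_bound = ko$ub, k_close_upper_bound = kc$ub
  ), class = "gate_rates")
}

#' @export
print.gate_rates <- function(x, ...) {
  fmt <- function(k, n, t, ub, lab) {
    if (is.na(k)) return(sprintf("  %s: state never visited\n", lab))
    sprintf("  %s %s %.4g s^-1  (%d events / %.4g s)\n",
            lab, if (ub) "<" else "=", k, n, t)
  }
  cat("Transition-count rate estimates\n")
  cat(fmt(x$k_open, x$n_opening, x$time_closed_s, x$k_open_upper_bound, "k_open "))
  cat(fmt(x$k_close, x$n_closing, x$time_open_s, x$k_close_upper_bound, "k_close"))
  invisible(x)
}

#' Convert a rate to an activation free energy (Eyring)
#'
#' `dG = -RT ln(k h / (kB T))`, i.e. transition-state theory with unit
#' transmission coefficient and prefactor `kB T / h` (~6.21e12 s^-1 at
#' 298 K). Rates above the prefactor give a negative barrier and are
#' flagged with a warning.
#'
#' @param k Rate constant, s^-1 (> 0; vectorised).
#' @param temperature Temperature, kelvin.
#' @param prefactor Attempt frequency, s^-1; defaults to
#'   [eyring_prefactor()] at `temperature`.
#' @return Barrier height(s) in kcal/mol.
#' @examples
#' barrier_from_rate(1.1e6)            # ~9.2 kcal/mol at 298 K
#' rate_from_barrier(9.2)              # ~1.1e6 s^-1
#' @export
barrier_from_rate <- function(k, temperature = 298,
                              prefactor = eyring_prefactor(temperature)) {
  if (any(k <= 0)) abort("`k` must be > 0")
  dg <- -.rt_kcal(temperature) * log(k / prefactor)
  if (any(dg < 0)) warn("rate exceeds the prefactor: negative barrier")
  dg
}

#' @rdname barrier_from_rate
#' @param dg Barrier height in kcal/mol.
#' @export
rate_from_barrier <- function(dg, temperature = 298,
                              prefactor = eyring_prefactor(temperature)) {
  prefactor * exp(-dg / .rt_kcal(temperature))
}

#' Barrier estimates from a digitised trajectory
#'
#' Convenience wrapper: [transition_rates()] followed by
#' [barrier_from_rate()] for both directions.
#'
#' @param seq A `gate_states` object.
#' @param temperature Temperature, kelvin.
#' @return A tibble with columns `direction`, `k_s`, `n_events`,
#'   `barrier_kcal`, `upper_bound` (for a zero-transition state the rate is
#'   an upper bound, hence the barrier a lower bound).
#' @export
gate_barriers <- function(seq, temperature = 298) {
  r <- transition_rates(seq)
  tibble(
    direction = c("opening", "closing"),
    k_s = c(r$k_open, r$k_close),
    n_events = c(r$n_opening, r$n_closing),
    upper_bound = c(r$k_open_upper_bound, r$k_close_upper_bound),
    barrier_kcal = vapply(c(r$k_open, r$k_close), function(k) {
      if (is.na(k)) NA_real_ else barrier_from_rate(k, temperature)
    }, numeric(1))
  )
}
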