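# Two-state digitisation, transition-count rates, and Eyring conversions.

test_that("frame-wise thresholding at 12 A assigns states correctly", {
  traj <- tibble::tibble(time_ps = 0:4 * 100,
                         distance_A = c(8, 13, 5, 14, 11))
  ds <- digitize_gate(traj)
  expect_equal(ds$states$state, c("closed", "open", "closed", "open", "closed"))

  all_closed <- tibble::tibble(time_ps = 0:99 * 100,
                               distance_A = runif(100, 5, 9))
  ds2 <- digitize_gate(all_closed)
  expect_equal(nrow(ds2$dwells), 1)
  expect_equal(ds2$dwells$state, "closed")
  # dwell durations account for the whole trajectory
  expect_equal(sum(ds2$dwells$n_frames), 100)
})

test_that("min_dwell suppresses emission-noise recrossings against the hidden truth", {
  traj <- sim_gate_trajectory(5e5, 5e5, dt_ps = 100, duration_s = 4e-5,
                              closed_mean = 7, open_mean = 14,
                              emission_sd = 1, seed = 41)
  true_transitions <- sum(diff(as.integer(traj$state_true == "open")) != 0)
  raw <- sum(diff(as.integer(digitize_gate(traj)$states$state == "open")) != 0)
  cleaned <- sum(diff(as.integer(
    digitize_gate(traj, min_dwell = 3)$states$state == "open")) != 0)
  spurious_raw <- raw - true_transitions
  spurious_cleaned <- max(cleaned - true_transitions, 0)
  expect_gt(spurious_raw, 0)
  expect_lt(spurious_cleaned, 0.1 * spurious_raw)

  # occupancy tracks the hidden state when the bands are well separated
  occ_est <- mean(digitize_gate(traj, min_dwell = 3)$states$state == "open")
  occ_true <- mean(traj$state_true == "open")
  n_dwell <- 4e-5 * 5e5
  expect_lt(abs(occ_est - occ_true), 3 * sqrt(0.25 / n_dwell) + 0.03)
})

test_that("transition counting divides events by state-resident time", {
  # 2 opening events over 30 ns closed -> 6.67e7 s^-1
  st <- c(rep(5, 100), rep(14, 50), rep(5, 200), rep(14, 50))
  traj <- tibble::tibble(time_ps = seq_along(st) * 100 - 100, distance_A = st)
  r <- transition_rates(digitize_gate(traj))
  expect_equal(r$n_opening, 2)
  expect_equal(r$time_closed_s, 300 * 100e-12)
  expect_equal(r$k_open, 2 / 30e-9, tolerance = 1e-10)
  expect_lte(abs(r$n_opening - r$n_closing), 1)

  # no transitions: one-sided upper bound, not a failure
  flat <- tibble::tibble(time_ps = 0:9999 * 100, distance_A = 7)
  rf <- transition_rates(digitize_gate(flat))
  expect_true(rf$k_open_upper_bound)
  expect_equal(rf$k_open, 1 / 1e-6, tolerance = 1e-3)
  expect_error(transition_rates(digitize_gate(flat[1, ])), "two frames")
})

test_that("rates estimated from Gillespie trajectories match the truth within 3 sd", {
  k_open <- 2e6; k_close <- 1e6
  traj <- sim_gate_trajectory(k_open, k_close, dt_ps = 50, duration_s = 1e-4,
                              seed = 57)
  r <- transition_rates(digitize_gate(traj, min_dwell = 4))
  # Poisson counting error: sd(k)/k ~ 1/sqrt(n)
  expect_lt(abs(r$k_open - k_open), 3 * k_open / sqrt(r$n_opening))
  expect_lt(abs(r$k_close - k_close), 3 * k_close / sqrt(r$n_closing))
})

test_that("Eyring conversion is exact and self-inverse", {
  kbt_h <- eyring_prefactor(298)
  expect_equal(kbt_h, 6.21e12, tolerance = 1e-3)
  expect_equal(barrier_from_rate(kbt_h, 298), 0)
  # 9.2 kcal/mol <-> ~1.1e6 s^-1 at 298 K
  expect_equal(rate_from_barrier(9.2, 298), 1.1e6, tolerance = 0.02)
  for (dg in seq(0, 16, 2)) {
    expect_equal(barrier_from_rate(rate_from_barrier(dg, 310), 310), dg,
                 tolerance = 1e-12)
  }
  expect_warning(barrier_from_rate(1e13, 298), "negative barrier")
  expect_error(barrier_from_rate(0), "> 0")
})

test_that("the barrier -> rate -> trajectory -> barrier loop is unbiased", {
  # moderate barrier so that thousands of events accumulate quickly
  dg <- 6.5
  k <- rate_from_barrier(dg, 298)
  traj <- sim_gate_trajectory(k, k, dt_ps = 1, duration_s = 2e-6, seed = 71)
  b <- gate_barriers(digitize_gate(traj, min_dwell = 3), temperature = 298)
  open_row <- dplyr::filter(b, direction == "opening")
  rt_kcal <- 1.987204259e-3 * 298
  mc_sd <- rt_kcal / sqrt(open_row$n_events)
  expect_lt(abs(open_row$barrier_kcal - dg), 3 * mc_sd + 0.05)
})
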