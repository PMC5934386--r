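# Generators: determinism, noiseless exactness, and the statistical
# structure the downstream fits assume.

test_that("generators are byte-identical under a fixed seed and leave the global RNG alone", {
  t <- seq(0, 600, 30)
  a <- sim_exponential_trace(t, rate = 0.01, noise_sd = 0.05, seed = 7)
  b <- sim_exponential_trace(t, rate = 0.01, noise_sd = 0.05, seed = 7)
  expect_identical(a, b)
  expect_false(identical(
    a, sim_exponential_trace(t, rate = 0.01, noise_sd = 0.05, seed = 8)))

  g1 <- suppressWarnings(sim_gate_trajectory(1e6, 1e6, duration_s = 2e-6, seed = 3))
  g2 <- suppressWarnings(sim_gate_trajectory(1e6, 1e6, duration_s = 2e-6, seed = 3))
  expect_identical(g1, g2)

  set.seed(99); before <- runif(1)
  set.seed(99)
  invisible(sim_exponential_trace(t, rate = 0.01, noise_sd = 0.05, seed = 1))
  expect_identical(runif(1), before)
})

test_that("noiseless exponential traces pass through the exact curve", {
  t <- seq(0, 1200, 60)
  dec <- sim_exponential_trace(t, rate = 0.19 / 60, amplitude = 2, offset = 0.5)
  expect_equal(dec$intensity[1], 2.5)
  expect_equal(dec$intensity, 0.5 + 2 * exp(-0.19 / 60 * t))
  ris <- sim_exponential_trace(t, rate = 1, amplitude = 3, offset = 0.2,
                               mode = "rise")
  expect_equal(ris$intensity[1], 0.2) # t = 0 gives the offset
  expect_error(sim_exponential_trace(t, rate = -1), "rate")
  expect_error(sim_exponential_trace(t, rate = 1, noise_sd = 0.1), "seed")
})

test_that("aminolysis generator follows the quadratic neutral-lysine law", {
  lys <- c(10, 30, 50, 75) * 1e-3
  zero <- sim_aminolysis_rates(lys, kcat1 = 0, kcat2 = 0)
  expect_true(all(zero$k_obs == 0))
  lin <- sim_aminolysis_rates(lys, kcat1 = 10, kcat2 = 0)
  expect_equal(lin$k_obs, 10 * lin$lys_neutral)
  expect_error(sim_aminolysis_rates(3e-2, kcat1 = 1, kcat2 = 1), "two")
})

test_that("work ensembles satisfy the second-order Jarzynski construction", {
  pmf <- pmf_gaussian_barrier(seq(0, 10, 0.5), barrier = 4)
  exact <- sim_work_ensemble(pmf, sigma_w = 0, n_runs = 3)
  expect_equal(
    dplyr::filter(exact, run == 2)$work_kcal, pmf$g_kcal, tolerance = 1e-12)

  flat <- tibble::tibble(position_A = seq(0, 5, 0.5), g_kcal = 0)
  w <- sim_work_ensemble(flat, sigma_w = 1, n_runs = 4000, seed = 5)
  beta <- 1 / (1.987204259e-3 * 298)
  mean_w <- mean(w$work_kcal)
  # mean work should be beta/2 ~ 0.844 kcal/mol; se ~ 1/sqrt(n_draws)
  se <- 1 / sqrt(nrow(w))
  expect_lt(abs(mean_w - beta / 2), 4 * se)
  expect_error(
    sim_work_ensemble(dplyr::arrange(flat, dplyr::desc(position_A)),
                      sigma_w = 1, n_runs = 5, seed = 1), "increasing")
})

test_that("gate trajectories follow the two-state Markov construction", {
  stuck <- suppressWarnings(sim_gate_trajectory(k_open = 0, k_close = 1e6,
                                                duration_s = 1e-6, seed = 2))
  expect_true(all(stuck$state_true == "closed"))

  traj <- sim_gate_trajectory(1e6, 1e6, dt_ps = 100, duration_s = 4e-5,
                              seed = 11)
  occ <- mean(traj$state_true == "open")
  # symmetric rates: long-run occupancy 1/2; allow 3 sd with the effective
  # number of dwells as the sample size
  n_dwell <- 4e-5 * 1e6
  expect_lt(abs(occ - 0.5), 3 * sqrt(0.25 / n_dwell))
  expect_warning(sim_gate_trajectory(1e3, 1e3, duration_s = 1e-6, seed = 1),
                 "dwells")
})

test_that("titration lineshape generator rejects mismatched concentration arrays", {
  expect_error(
    sim_titration_lineshapes(2.9e7, 5886, protein_totals = rep(4e-4, 3),
                             ligand_totals = rep(1e-4, 4)), "equal length")
})
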