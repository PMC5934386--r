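# Exponential fits, the neutral-lysine rate law, and the ASA trend.

test_that("noiseless exponential fits recover the generating rate to 1e-8", {
  for (rate_min in c(0.19, 0.001)) {
    for (mode in c("decay", "rise")) {
      t_half <- log(2) / (rate_min / 60)
      tt <- seq(0, 5 * t_half, length.out = 40)
      tr <- sim_exponential_trace(tt, rate = rate_min / 60, amplitude = 1.7,
                                  offset = 0.3, mode = mode)
      f <- fit_exponential(tr, mode = mode)
      expect_equal(f$rate_s, rate_min / 60, tolerance = 1e-8)
      expect_equal(f$amplitude, 1.7, tolerance = 1e-6)
      expect_equal(f$offset, 0.3, tolerance = 1e-6)
    }
  }
})

test_that("noisy refits recover the rate within 3 fitted standard errors", {
  tt <- seq(0, 5 * log(2) / (0.001 / 60), length.out = 50)
  tr <- sim_exponential_trace(tt, rate = 0.001 / 60, mode = "decay",
                              noise_sd = 0.02, seed = 21)
  f <- fit_exponential(tr, mode = "decay")
  expect_lt(abs(f$rate_s - 0.001 / 60), 3 * f$rate_se)
})

test_that("degenerate traces are flagged, not silently fit", {
  flat <- tibble::tibble(time_s = 0:9 * 10, intensity = rep(1, 10))
  f <- fit_exponential(flat)
  expect_false(f$converged)
  expect_match(f$flag, "unidentifiable")
  expect_true(is.na(f$rate_s))
  expect_error(fit_exponential(flat[1:3, ]), "4 points")
})

test_that("apparent conjugation rate is k_obs over [E1]", {
  # 0.594 min^-1 at 330 nM E1 -> 1.8e6 M^-1 min^-1
  expect_equal(apparent_rate(0.594, 330e-9), 1.8e6, tolerance = 1e-3)
  expect_equal(apparent_rate(0, 330e-9), 0)
  expect_equal(apparent_rate(1, 2 * 330e-9), apparent_rate(1, 330e-9) / 2)
  expect_error(apparent_rate(1, 0), "> 0")
})

test_that("neutral-lysine fraction follows Henderson-Hasselbalch", {
  expect_equal(neutral_lysine(0.1, pH = 10.54, pKa = 10.54), 0.05)
  expect_equal(neutral_lysine(30e-3, pH = 8.0, pKa = 10.54),
               8.63e-5, tolerance = 1e-3)
  expect_equal(neutral_lysine(0), 0)
})

test_that("the linearised aminolysis fit recovers both catalytic constants", {
  lys <- c(10, 20, 30, 50, 75) * 1e-3
  s <- sim_aminolysis_rates(lys, kcat1 = 10, kcat2 = 1e8)
  f <- fit_aminolysis(s)
  expect_equal(f$kcat1, 10, tolerance = 1e-6)
  expect_equal(f$kcat2, 1e8, tolerance = 1e-6)

  # permutation invariance (to floating-point summation order)
  f_perm <- fit_aminolysis(s[c(3, 1, 5, 2, 4), ])
  expect_equal(c(f$kcat1, f$kcat2), c(f_perm$kcat1, f_perm$kcat2),
               tolerance = 1e-9)

  # unit rescaling: lysine in mM with constants rescaled accordingly
  s_mm <- dplyr::mutate(s, lys_total = lys_total * 1e3)
  f_mm <- fit_aminolysis(s_mm)
  expect_equal(f_mm$kcat1 * 1e3, f$kcat1, tolerance = 1e-9)
  expect_equal(f_mm$kcat2 * 1e6, f$kcat2, tolerance = 1e-9)

  # pure first-order data gives a zero slope
  f_lin <- fit_aminolysis(sim_aminolysis_rates(lys, kcat1 = 10, kcat2 = 0))
  expect_lt(abs(f_lin$kcat2), 1e-4 * f_lin$kcat1 / max(s$lys_neutral))

  expect_error(
    fit_aminolysis(tibble::tibble(lys_total = rep(0.03, 4), k_obs = 1:4)),
    "distinct")
})

test_that("aminolysis constants are recovered within 3 se under assay noise", {
  lys <- seq(10, 75, length.out = 8) * 1e-3
  s <- sim_aminolysis_rates(lys, kcat1 = 10, kcat2 = 1e8,
                            noise_sd = 0.02, seed = 31)
  f <- fit_aminolysis(s)
  expect_lt(abs(f$kcat1 - 10), 3 * f$kcat1_se)
  expect_lt(abs(f$kcat2 - 1e8), 3 * f$kcat2_se)
})

test_that("rate versus side-chain ASA regression behaves", {
  asa <- asa_scale()
  res <- c("A", "V", "I")
  rates <- tibble::tibble(residue = res, rate = 0.01 * asa[res] + 2)
  f <- fit_rate_vs_asa(rates)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_gt(f$slope, 0)

  const <- tibble::tibble(residue = c("A", "V", "I", "L"), rate = 5)
  expect_equal(fit_rate_vs_asa(const)$slope, 0, tolerance = 1e-12)

  expect_error(
    fit_rate_vs_asa(tibble::tibble(residue = c("A", "V", "Z"), rate = 1:3)),
    "Z")
})
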