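# Correlation-function fitting, spectral densities, 15N rate
# back-calculation and tau_c estimation.

test_that("correlation model validates its amplitude constraints", {
  expect_error(correlation_model(0.5, 0.2, 0.2), "sum to 1")
  expect_error(correlation_model(1.2, -0.2, 0), "\\[0, 1\\]")
  expect_error(correlation_model(0.8, 0.2, tau1 = -1), "tau1")
  m <- correlation_model(0.8, 0.15, 0.05, tau1 = 50e-12, tau2 = 2e-9)
  expect_equal(correlation_function(m, 0), 1)
})

test_that("five-parameter correlation fits recover generating models", {
  lags <- seq(0, 20e-9, length.out = 500)

  rigid <- fit_correlation(tibble::tibble(lag_s = lags, c = rep(1, 500)))
  expect_equal(rigid$a_inf, 1)
  expect_match(rigid$flag, "rigid")

  one <- correlation_model(0.8, 0.2, tau1 = 100e-12)
  f1 <- fit_correlation(tibble::tibble(lag_s = lags,
                                       c = correlation_function(one, lags)))
  expect_equal(f1$a_inf, 0.8, tolerance = 1e-4)
  expect_equal(f1$a1 + f1$a2, 0.2, tolerance = 1e-3)
  # the dominant decay sits at 100 ps; the second amplitude is negligible
  tau_dom <- if (f1$a1 >= f1$a2) f1$tau1 else f1$tau2
  expect_equal(tau_dom, 100e-12, tolerance = 0.01 * 100e-12)
  expect_lt(min(f1$a1, f1$a2), 1e-3)

  two <- correlation_model(0.7, 0.2, 0.1, tau1 = 50e-12, tau2 = 2e-9)
  f2 <- fit_correlation(tibble::tibble(lag_s = lags,
                                       c = correlation_function(two, lags)))
  expect_equal(f2$a_inf, 0.7, tolerance = 0.05)
  expect_equal(min(f2$tau1, f2$tau2), 50e-12, tolerance = 0.05 * 50e-12)
  expect_equal(max(f2$tau1, f2$tau2), 2e-9, tolerance = 0.05 * 2e-9)
})

test_that("spectral density matches a numerical cosine transform to 1e-4", {
  cases <- list(
    list(a_inf = 1, a1 = 0, a2 = 0, tau1 = Inf, tau2 = Inf),
    list(a_inf = 0.8, a1 = 0.2, a2 = 0, tau1 = 100e-12, tau2 = Inf),
    list(a_inf = 0.7, a1 = 0.2, a2 = 0.1, tau1 = 50e-12, tau2 = 2e-9)
  )
  tauc <- 17e-9
  freqs <- 2 * pi * c(0, 60.8e6, 600e6)
  for (cs in cases) {
    m <- correlation_model(cs$a_inf, cs$a1, cs$a2,
                           tau1 = if (cs$a1 > 0) cs$tau1 else NULL,
                           tau2 = if (cs$a2 > 0) cs$tau2 else NULL)
    for (w in freqs) {
      expect_equal(
        spectral_density(m, w, tauc),
        simpson_cos_J(cs$a_inf, cs$a1, cs$a2, cs$tau1, cs$tau2, tauc, w),
        tolerance = 1e-4)
    }
  }
  # rigid limit at omega = 0: J = (2/5) tauc; and J decreases with omega
  expect_equal(spectral_density(correlation_model(1), 0, tauc), 0.4 * tauc)
  js <- spectral_density(correlation_model(1), 2 * pi * 10^seq(6, 9, 0.5), tauc)
  expect_true(all(diff(js) < 0))
})

test_that("rigid-rotor back-calculation matches the closed form to 1e-6 over 1-50 ns", {
  rigid <- correlation_model(1)
  for (tc in c(1, 5, 17, 30, 50) * 1e-9) {
    got <- calc_relaxation(rigid, tc, field_mhz = 600)
    want <- rigid_relax_oracle(tc, 600)
    expect_equal(got$r1_s, want$r1, tolerance = 1e-6)
    expect_equal(got$r2_s, want$r2, tolerance = 1e-6)
    expect_equal(got$noe, want$noe, tolerance = 1e-6)
  }
  # R2 grows monotonically with tauc beyond 1 ns
  r2s <- vapply(seq(1, 50, 5) * 1e-9,
                function(tc) calc_relaxation(rigid, tc)$r2_s, numeric(1))
  expect_true(all(diff(r2s) > 0))
  # extreme narrowing: NOE tends to 1 + (gH/gN) * d2/4 * 5 tauc / R1-limit form
  tiny <- calc_relaxation(rigid, 1e-12)
  oracle_tiny <- rigid_relax_oracle(1e-12)
  expect_equal(tiny$noe, oracle_tiny$noe, tolerance = 1e-9)
})

test_that("tau_c from R2/R1 inverts the back-calculation exactly", {
  rigid <- correlation_model(1)
  for (tc in c(1, 5, 16, 17, 18, 50) * 1e-9) {
    r <- calc_relaxation(rigid, tc)
    est <- tauc_from_r2r1(tibble::tibble(residue = "X", r1_s = r$r1_s,
                                         r2_s = r$r2_s))
    expect_equal(est$tauc_s, tc, tolerance = 1e-4)
  }
  # residues at 16 and 18 ns average to 17 ns; identical ratios agree
  r16 <- calc_relaxation(rigid, 16e-9); r18 <- calc_relaxation(rigid, 18e-9)
  est <- tauc_from_r2r1(tibble::tibble(
    residue = c("a", "b"), r1_s = c(r16$r1_s, r18$r1_s),
    r2_s = c(r16$r2_s, r18$r2_s)))
  expect_equal(est$tauc_s, 17e-9, tolerance = 1e-4)
  # unattainable ratios are excluded with a message
  expect_message(
    est2 <- tauc_from_r2r1(tibble::tibble(
      residue = c("ok", "bad"), r1_s = c(r16$r1_s, 1), r2_s = c(r16$r2_s, 1e6))),
    "excluded")
  expect_equal(est2$excluded, "bad")
})

test_that("population weighting combines rates, and NOE via cross-relaxation", {
  m_open <- correlation_model(0.6, 0.4, tau1 = 200e-12)
  m_closed <- correlation_model(0.9, 0.1, tau1 = 50e-12)
  open <- calc_relaxation(m_open, 17e-9)
  closed <- calc_relaxation(m_closed, 17e-9)

  expect_equal(population_weighted_rates(open, closed, 1), open[1:4])
  expect_equal(population_weighted_rates(open, open, 0.3)$r1_s, open$r1_s)

  w <- population_weighted_rates(open, closed, 0.25)
  expect_equal(w$r1_s, 0.25 * open$r1_s + 0.75 * closed$r1_s)
  expect_equal(w$r2_s, 0.25 * open$r2_s + 0.75 * closed$r2_s)
  # NOE: weighted sigma over weighted R1, not a weighted ratio
  g <- -2.7126189e7 / 2.6752218744e8
  sig <- 0.25 * (open$noe - 1) * open$r1_s * g +
    0.75 * (closed$noe - 1) * closed$r1_s * g
  expect_equal(w$noe, 1 + sig / (g * w$r1_s))
  expect_false(isTRUE(all.equal(w$noe, 0.25 * open$noe + 0.75 * closed$noe)))

  # simple arithmetic check on the convex combination
  a <- tibble::tibble(r1_s = 1, r2_s = 10, noe = 0.8, field_mhz = 600)
  b <- tibble::tibble(r1_s = 2, r2_s = 20, noe = 0.8, field_mhz = 600)
  expect_equal(population_weighted_rates(a, b, 0.25)$r1_s, 1.75)
  expect_error(population_weighted_rates(a, dplyr::mutate(b, field_mhz = 500), 0.5),
               "same field")
})
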