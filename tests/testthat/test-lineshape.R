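# Bloch-McConnell two-site exchange lineshapes: closed-form limits,
# intensity conservation, and kon/koff recovery from titration series.

test_that("without ligand the spectrum is a Lorentzian at the free shift", {
  freq <- seq(-60, 60, length.out = 4001)
  sp <- simulate_lineshape(2.9e7, 5886, shift_free_hz = 0, shift_bound_hz = 120,
                           r2_free = 5, r2_bound = 8,
                           protein_total = 420e-6, ligand_total = 0,
                           freq_hz = freq)
  peak <- sp$freq_hz[which.max(sp$intensity)]
  expect_lt(abs(peak), diff(freq)[1])
  # FWHM = R2/pi Hz
  half <- max(sp$intensity) / 2
  above <- range(sp$freq_hz[sp$intensity >= half])
  expect_equal(diff(above), 5 / pi, tolerance = 0.02)
  # matches the exact Lorentzian pointwise (both normalised on this grid)
  exact <- 5 / (5^2 + (2 * pi * sp$freq_hz)^2)
  exact <- exact / trapz(sp$freq_hz, exact)
  expect_equal(sp$intensity, exact, tolerance = 1e-6)
})

test_that("integrated intensity is 1 across all exchange regimes", {
  freq <- seq(-400, 520, length.out = 3000)
  for (koff in 10^c(1, 2, 3, 4, 6)) {
    sp <- simulate_lineshape(koff / 2e-4, koff, 0, 120, 5, 5,
                             protein_total = 420e-6, ligand_total = 560e-6,
                             freq_hz = freq)
    expect_equal(trapz(sp$freq_hz, sp$intensity), 1, tolerance = 1e-6)
  }
})

test_that("slow exchange gives two Lorentzians weighted by the populations", {
  kd <- 2e-4
  koff <- 0.05 # far below the 120 Hz shift separation
  freq <- seq(-60, 180, length.out = 6000)
  sp <- simulate_lineshape(koff / kd, koff, 0, 120, 5, 5,
                           protein_total = 420e-6, ligand_total = 560e-6,
                           freq_hz = freq)
  pb <- attr(sp, "p_bound")
  lor <- function(f, f0, r2) (1 / pi) * r2 / (r2^2 + (2 * pi * (f - f0))^2) * 2 * pi
  two <- (1 - pb) * lor(freq, 0, 5) + pb * lor(freq, 120, 5)
  expect_equal(sp$intensity, two, tolerance = 5e-3)
})

test_that("fast exchange collapses to one line at the population-weighted shift", {
  kd <- 2e-4
  koff <- 1e7
  freq <- seq(-60, 180, length.out = 8001)
  sp <- simulate_lineshape(koff / kd, koff, 0, 120, 5, 5,
                           protein_total = 420e-6, ligand_total = 560e-6,
                           freq_hz = freq)
  pb <- attr(sp, "p_bound")
  peak <- sp$freq_hz[which.max(sp$intensity)]
  expect_equal(peak, pb * 120, tolerance = 0.1)
  # symmetric 50/50 fast exchange with shifts +/-100 Hz peaks at 0
  sp2 <- simulate_lineshape(5e12, 1e9, -100, 100, 5, 5,
                            protein_total = 420e-6, ligand_total = 1e-1,
                            freq_hz = seq(-150, 150, length.out = 2001))
  pk2 <- sp2$freq_hz[which.max(sp2$intensity)]
  pb2 <- attr(sp2, "p_bound")
  expect_equal(pk2, -100 + 200 * pb2, tolerance = 0.5)
})

test_that("exchange-broadened width matches the fast-exchange expansion", {
  kd <- 2e-4
  koff <- 5e4
  freq <- seq(-120, 240, length.out = 20001)
  sp <- simulate_lineshape(koff / kd, koff, 0, 120, 5, 5,
                           protein_total = 420e-6, ligand_total = 560e-6,
                           freq_hz = freq)
  pb <- attr(sp, "p_bound")
  lf <- attr(sp, "l_free_M")
  kex <- koff / kd * lf + koff
  dw <- 2 * pi * 120
  r2_eff <- 5 + pb * (1 - pb) * dw^2 / kex
  half <- max(sp$intensity) / 2
  fwhm <- diff(range(sp$freq_hz[sp$intensity >= half]))
  expect_equal(fwhm, r2_eff / pi, tolerance = 0.02)
})

test_that("titration lineshape fitting recovers kon and koff within 5%", {
  ls <- sim_titration_lineshapes(kon = 2.9e7, koff = 5886)
  fit <- fit_exchange(ls)
  expect_lt(abs(fit$koff - 5886) / 5886, 0.05)
  expect_lt(abs(fit$kon - 2.9e7) / 2.9e7, 0.05)
  # internal consistency: KD equals koff/kon by construction
  expect_equal(fit$kd_M, fit$koff / fit$kon, tolerance = 1e-12)
})

test_that("koff scaled tenfold at fixed KD is recovered tenfold larger", {
  base <- fit_exchange(sim_titration_lineshapes(kon = 5e6, koff = 1000))
  fast <- fit_exchange(sim_titration_lineshapes(kon = 5e7, koff = 10000))
  expect_equal(fast$koff / base$koff, 10, tolerance = 0.15)
})

test_that("underdetermined input is rejected", {
  ls <- sim_titration_lineshapes(2.9e7, 5886)
  expect_error(fit_exchange(dplyr::filter(ls, point == 1)), "3 titration")
})

test_that("lineshape KD agrees with the isotherm KD on self-consistent data", {
  kon <- 2.9e7; koff <- 5886
  fit <- fit_exchange(sim_titration_lineshapes(kon, koff))
  tt <- sim_csp_titration(koff / kon, c(G173 = 0.12, F174 = 0.2))
  iso <- fit_kd(tt)
  expect_lt(abs(fit$kd_M / iso$kd_M - 1), 0.05)
})
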