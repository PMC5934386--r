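# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive each quantity with a different method
# (fixed-step RK4, Simpson cosine transform, closed-form limits) and never
# call the code paths they validate.

# fixed-step classical RK4 for the six-species chain-synthesis ODEs,
# derivatives written out independently of the package
rk4_chain <- function(kon, koff, kh2o, kub2, y0, t_end, h, t_out) {
  deriv <- function(y) {
    E2 <- y[1]; TE <- y[2]; UT <- y[3]; EU <- y[4]; Ub <- y[5]
    c(
      kh2o * TE - kon * E2 * Ub + koff * EU + kub2 * UT,
      koff * UT - kon * TE * Ub - kh2o * TE,
      -koff * UT + kon * TE * Ub - kub2 * UT - kh2o * UT,
      -koff * EU + kon * E2 * Ub + kh2o * UT,
      koff * UT + koff * EU - kon * TE * Ub - kon * E2 * Ub +
        kh2o * TE + kh2o * UT,
      kub2 * UT
    )
  }
  n_steps <- ceiling(t_end / h)
  t <- 0
  y <- y0
  out <- matrix(NA_real_, nrow = length(t_out), ncol = 6)
  next_out <- 1
  record <- function(tq) {
    while (next_out <= length(t_out) && t_out[next_out] <= tq + 1e-12) {
      out[next_out, ] <<- y
      next_out <<- next_out + 1
    }
  }
  record(t)
  for (i in seq_len(n_steps)) {
    k1 <- deriv(y)
    k2 <- deriv(y + h / 2 * k1)
    k3 <- deriv(y + h / 2 * k2)
    k4 <- deriv(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
    record(t)
  }
  colnames(out) <- c("E2", "E2~Ub", "Ub.E2~Ub", "E2.Ub", "Ub", "Ub2")
  out
}

# Simpson-rule cosine transform of a plateau + two-exponential correlation
# decay multiplied by overall tumbling, the time-domain counterpart of the
# model spectral density
simpson_cos_J <- function(a_inf, a1, a2, tau1, tau2, tauc, omega) {
  c_fun <- function(t) {
    v <- a_inf
    if (a1 > 0) v <- v + a1 * exp(-t / tau1)
    if (a2 > 0) v <- v + a2 * exp(-t / tau2)
    v
  }
  t_end <- 40 * tauc
  period <- if (omega > 0) 2 * pi / omega else Inf
  dt <- min(period / 100, tauc / 200)
  n <- ceiling(t_end / dt)
  if (n %% 2 == 1) n <- n + 1
  tt <- seq(0, t_end, length.out = n + 1)
  f <- c_fun(tt) * exp(-tt / tauc) * cos(omega * tt)
  hh <- tt[2] - tt[1]
  w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
  (2 / 5) * sum(w * f) * hh / 3
}

# closed-form rigid-rotor (single-Lorentzian) 15N relaxation rates,
# written independently of the package's model machinery
rigid_relax_oracle <- function(tauc, field_mhz = 600,
                               r_nh = 1.02e-10, csa_ppm = -172) {
  mu0_4pi <- 1e-7; hbar <- 1.054571817e-34
  gh <- 2.6752218744e8; gn <- -2.7126189e7
  d <- mu0_4pi * gh * abs(gn) * hbar / r_nh^3
  wh <- 2 * pi * field_mhz * 1e6
  wn <- wh * gn / gh
  J <- function(w) 0.4 * tauc / (1 + (w * tauc)^2)
  c2 <- (wn * csa_ppm * 1e-6 / sqrt(3))^2
  r1 <- d^2 / 4 * (J(wh - wn) + 3 * J(wn) + 6 * J(wh + wn)) + c2 * J(wn)
  r2 <- d^2 / 8 * (4 * J(0) + J(wh - wn) + 3 * J(wn) + 6 * J(wh) +
                     6 * J(wh + wn)) + c2 / 6 * (4 * J(0) + 3 * J(wn))
  noe <- 1 + (gh / gn) * (d^2 / 4) * (6 * J(wh + wn) - J(wh - wn)) / r1
  list(r1 = r1, r2 = r2, noe = noe)
}

# trapezoid integral, for intensity-conservation checks
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
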