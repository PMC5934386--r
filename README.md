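# gatekin

Quantitative analysis of active-site gate dynamics in
ubiquitin-conjugating (E2) enzymes.

E2 enzymes catalyse the central step of ubiquitination: transfer of
ubiquitin from a thioester on the E2 active-site cysteine to a substrate
lysine. A loop that buttresses the active site — the *gate* — fluctuates
between a closed, catalytically competent conformation and an open one,
and the balance of opening and closing rates tunes catalysis.
Characterising that balance for an enzyme such as E2-25K takes four kinds
of quantitative data, and `gatekin` implements the analysis for all of
them, plus seeded generators of synthetic data for every input class so
the entire pipeline is testable against known ground truth:

* **Enzyme kinetics** — exponential fits of conjugation, hydrolysis and
  aminolysis time courses (`fit_exponential`, `apparent_rate`); the
  quadratic neutral-lysine aminolysis rate law
  `k_obs = kcat1·[lys⁰] + kcat2·[lys⁰]²` (`fit_aminolysis`,
  `neutral_lysine`); and a six-species coupled-ODE model of K48-linked
  di-ubiquitin synthesis with bounded least-squares recovery of the
  catalytic constant k<sub>Ub2</sub> (`chain_model`,
  `simulate_chain_synthesis`, `fit_kub2`).
* **NMR binding** — combined amide chemical shift perturbations
  Δδ = √((Δδ¹Hᴺ)² + (Δδ¹⁵N/5)²) and the mean + 1σ significance rule
  (`csp`, `significant_csps`); global 1:1 isotherm fitting with exact
  ligand depletion (`fit_kd`); Bloch–McConnell two-site exchange
  lineshape simulation and simultaneous titration fitting for
  k<sub>on</sub>/k<sub>off</sub> (`simulate_lineshape`, `fit_exchange`).
* **¹⁵N relaxation** — five-parameter correlation-function fits,
  model spectral densities, dipolar + CSA back-calculation of
  R₁/R₂/NOE, τ<sub>c</sub> from the R₂/R₁ ratio, and open/closed
  population weighting (`fit_correlation`, `spectral_density`,
  `calc_relaxation`, `tauc_from_r2r1`, `population_weighted_rates`).
* **Gate dynamics** — two-state digitisation of distance trajectories at
  a 12 Å cutoff, transition-count rate estimation with honest upper
  bounds for quiet trajectories, Eyring conversion
  ΔG‡ = −RT·ln(k·h/k<sub>B</sub>T), and steered-work free-energy
  profiles via the second-order Jarzynski cumulant expansion
  ΔG(x) = ⟨W⟩ − (β/2)·Var W with bootstrap confidence intervals
  (`digitize_gate`, `transition_rates`, `barrier_from_rate`,
  `pmf_from_work`).

All user-facing functions take a data frame first and return tibbles, so
stages chain with the pipe; fitted objects support `tidy()`, `glance()`
and `autoplot()`.

## Worked example

Recover a dissociation constant from a synthetic titration, exchange
rates from lineshapes, and the chain-formation rate constant from a noisy
progress curve:

```r
library(gatekin)
library(dplyr)

# 6-point CSP titration generated at KD = 206 uM, then refit
titr <- sim_csp_titration(kd = 206e-6,
                          dd_max = c(G173 = 0.12, F174 = 0.08, V190 = 0.20))
fit_kd(titr)
#> 1:1 binding isotherm fit (global mode)
#>   KD = 206 uM (se 8.15e-07 uM), 3 residue(s)

# titration lineshapes at kon = 2.9e7 M^-1 s^-1, koff = 5886 s^-1
fit_exchange(sim_titration_lineshapes(kon = 2.9e7, koff = 5886))
#>   kon  = 2.9e+07 M^-1 s^-1
#>   koff = 5886 s^-1
#>   KD = koff/kon = 203 uM

# di-ubiquitin synthesis at k_Ub2 = 0.002 s^-1 with 3% noise, then refit
m <- chain_model(kon = 2.9e7, koff = 5886, k_h2o = 0.001 / 60,
                 k_ub2 = 0.002, init = c(`E2~Ub` = 8e-6, Ub = 100e-6))
ub2 <- sim_chain_traces(m, seq(0, 3600, 60), noise_sd = 0.03, seed = 7) |>
  filter(species == "Ub2", time_s > 0)
fit_kub2(transmute(ub2, time_s, conc_M),
         chain_model(2.9e7, 5886, 0.001 / 60, 0,
                     init = c(`E2~Ub` = 8e-6, Ub = 100e-6)))
#> Chain-formation rate fit
#>   k_Ub2 = 0.00198 s^-1 (se 2.43e-05), SSR = 3.039e-12, n = 60
```

The gate-opening barrier survives a full stochastic round trip — barrier
to Eyring rate, Gillespie trajectory, 12 Å digitisation, transition
counting, and back:

```r
k <- rate_from_barrier(9.2)          # 1.11e6 s^-1 at 298 K
traj <- sim_gate_trajectory(k, k, dt_ps = 100, duration_s = 240 / k,
                            seed = 7)
gate_barriers(digitize_gate(traj, cutoff = 12, min_dwell = 5))
#>   direction      k_s n_events upper_bound barrier_kcal
#> 1 opening   1134535.      131 FALSE               9.19
#> 2 closing   1294661.      130 FALSE               9.11
```

The numbers printed are estimates recovered from simulated data generated
at the stated true values: 206 µM, 5886 s⁻¹, 0.002 s⁻¹ and
9.2 kcal/mol respectively, so the small deviations show each estimator's
statistical error at realistic data sizes.

## Repository layout

```
R/                  implementation (one file per analysis area)
tests/testthat/     unit, property and end-to-end recovery tests
scripts/acceptance.R  headline recomputation script (see above)
vignettes/          methods vignette: models, assumptions, numerics
inst/extdata/       side-chain ASA scale (YAML)
```
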