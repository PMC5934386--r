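---
title: "Models and methods in gatekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in gatekin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatekin)
library(dplyr)
```

gatekin analyses the quantitative experiments used to characterise
active-site gate dynamics in ubiquitin-conjugating (E2) enzymes such as
E2-25K: fluorescence-detected enzyme kinetics, NMR titrations and exchange
lineshapes, backbone ^15^N relaxation, and molecular-dynamics-derived gate
trajectories and steered-work curves. Every analysis stage has a matching
seeded generator, so the whole pipeline can be exercised against known
ground truth without any external data. This vignette explains each model,
its assumptions and tunable parameters, the numerical choices made, and
what the synthetic data do and do not establish about real experiments.

## Enzyme kinetics

### Exponential assays

Thioester conjugation (E1-catalysed charging of the E2 with ubiquitin),
thioester hydrolysis, and lysine aminolysis are all followed as
fluorescence time courses and fit with the two-parameter exponential forms

$$ I(t) = c + A\,(1 - e^{-k_\mathrm{obs} t}) \quad\text{(build-up)},\qquad
   I(t) = c + A\,e^{-k_\mathrm{obs} t} \quad\text{(decay)}. $$

`fit_exponential()` estimates $(k_\mathrm{obs}, A, c)$ by
Levenberg-Marquardt with multi-start initialisation on the rate; amplitude
and offset are always fit freely, since the raw assay intensities are not
normalised. Internally every rate is in s^-1^ and every concentration in
molar; `per_minute()`/`per_second()` convert at the I/O boundary, because
the assay literature mixes min^-1^ and s^-1^. A constant trace is returned
flagged (`rate unidentifiable`) rather than as a silent zero. Conjugation
rates are compared across enzyme variants through the apparent
second-order constant $k_\mathrm{app} = k_\mathrm{obs}/[\mathrm{E1}]$
(`apparent_rate()`).

### Quadratic aminolysis rate law

Aminolysis of the E2~Ub thioester by free L-lysine depends on the
*neutral-amine* lysine concentration $[\mathrm{lys}^0]$, the fraction of
total lysine with a deprotonated side chain given by
Henderson-Hasselbalch (`neutral_lysine()`, default pKa 10.54). Observed
rates are quadratic,

$$ k_\mathrm{obs} = k_\mathrm{cat,1}[\mathrm{lys}^0]
   + k_\mathrm{cat,2}[\mathrm{lys}^0]^2, $$

so plotting $k_\mathrm{obs}/[\mathrm{lys}^0]$ against $[\mathrm{lys}^0]$
linearises the law; `fit_aminolysis()` performs that (optionally weighted)
regression, returning $k_\mathrm{cat,1}$ as the intercept and
$k_\mathrm{cat,2}$ as the slope. The reaction pH of the assay mixtures is
not fixed by the protocol we model, and the neutral fraction is extremely
sensitive to it, so pH is an explicit parameter (default 8.0, the
dialysis-buffer pH) rather than a hidden constant. The trend of catalytic
rate with side-chain hydrophobic surface at the gate position is
quantified by `fit_rate_vs_asa()` against a shipped theoretical
maximum-accessibility scale (Tien et al. 2013); any other ASA table can be
substituted, since published scales differ by construction.

### Di-ubiquitin chain synthesis

K48-linked Ub~2~ synthesis is modelled with six coupled species: free
enzyme E2, thioester E2~Ub, acceptor-bound thioester Ub·E2~Ub,
acceptor-bound free enzyme E2·Ub, free Ub, and product Ub~2~. Acceptor-Ub
binding to charged and uncharged enzyme shares one $k_{on}/k_{off}$ pair
(the binding site is the UBA domain, far from the active site), both
thioester forms hydrolyse with the same $k_{H_2O}$, and catalysis proceeds
from the acceptor-bound thioester with rate $k_{Ub_2}$. Two stoichiometric
sums — total enzyme and total ubiquitin equivalents — are exactly
conserved by the equations and are checked to 10^-8^ in the tests.

`simulate_chain_synthesis()` integrates the system with `deSolve::lsoda`
at rtol 10^-8^ and atol 10^-12^ M. The association term
($k_{on} \approx 3\times10^7$ M^-1^s^-1^ at ~100 µM Ub) relaxes on a
~10^-4^ s time scale while product forms over an hour, so the system is
moderately stiff and a stiff-capable adaptive method is the right tool.
`fit_kub2()` recovers $k_{Ub_2}$ by bounded scalar least squares on
[0, 10 s^-1^] over repeated integrations — a one-dimensional search,
because all other constants are fixed from independent measurements
(on/off rates from lineshape analysis, hydrolysis from its own assay). A
coarse log-spaced bracket precedes golden-section refinement so that the
optimum is not missed on the wide prior interval; the standard error comes
from the curvature of the residual profile, and flat traces are flagged.

## NMR binding analysis

### Chemical shift perturbations and the 1:1 isotherm

Combined amide CSPs use the conventional nitrogen scaling
$\Delta\delta = \sqrt{(\Delta\delta_{1H})^2 + (\Delta\delta_{15N}/5)^2}$
(`csp()`), and the interface-mapping significance rule is
$\Delta\delta > \bar{\Delta\delta} + 1\sigma$ (`significant_csps()`).

Because the titrations run protein (~420 µM) comparable to the
dissociation constant, free ligand cannot be approximated by total ligand:
`fit_kd()` uses the exact quadratic 1:1 mass balance at every point
(`fraction_bound()`). The default mode fits one global $K_D$ shared across
residues, with each residue's saturating shift $\Delta\delta_{max}$ solved
in closed form at any candidate $K_D$ — this makes the search
one-dimensional and immune to poor multi-parameter starts. Because an
"average $K_D$" can also mean the mean of per-residue fits, a
`per_residue` mode implements that reading; the two agree on
self-consistent data (verified in tests) and the package asserts neither
as *the* historical method. Fits with < 50% saturation at the top point
are flagged as poorly determined.

### Two-site exchange lineshapes

The free/bound exchange of an amide ^15^N resonance follows the
Bloch-McConnell equations; the absorption spectrum is

$$ S(\omega) = \mathrm{Re}\!\left[\mathbf{1}^{T}
   \left(i(\omega - \Omega) + R_2 - K\right)^{-1} \mathbf{p}\right], $$

with exchange matrix built from $k_{fb} = k_{on}[L]_\mathrm{free}$ and
$k_{bf} = k_{off}$ and populations from the depletion mass balance at
$K_D = k_{off}/k_{on}$. The 2x2 complex inverse is evaluated in closed
form, vectorised over the frequency grid (512 points by default), and
normalised to unit integrated intensity — conservation that holds in every
exchange regime and is tested to 10^-6^. Lineshapes are modelled in the
^15^N dimension only (1D slices), reflecting how well-separated titration
peaks are analysed in practice.

`fit_exchange()` fits all titration spectra simultaneously with shared
$k_{on}$, $k_{off}$, state shifts and R~2~ (one shared R~2~ by default —
the free and bound forms of a ~25 kDa protein relax similarly, and the
choice is exposed via `shared_r2 = FALSE`). The optimiser works in
$(\log k_{off}, \log K_D)$ so the physical constraint
$K_D = k_{off}/k_{on}$ holds by construction, runs from a 12-point
multi-start grid, and scales each model spectrum to the data by linear
least squares so arbitrary intensity units are accepted. In the
fast-exchange limit $k_{off}$ enters only through the exchange broadening
$p_f p_b \Delta\omega^2/k_{ex}$, so when that broadening is small compared
with R~2~ the rates are weakly determined; the fit then flags the
degeneracy and still reports $K_D$, which remains well determined by the
peak positions.

## ^15^N relaxation back-calculation

Amide-vector motion is modelled by a plateau plus two internal
exponentials, $C(t) = A_\infty + A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2}$
with $A_\infty + A_1 + A_2 = 1$ (`correlation_model()`,
`fit_correlation()`); this is the five-parameter form used to fit
correlation functions computed from 20-ns MD windows assigned to the open
or closed gate state. Combined with isotropic overall tumbling at
$\tau_c$, the spectral density is

$$ J(\omega) = \tfrac{2}{5}\left[
   \frac{A_\infty \tau_c}{1+(\omega\tau_c)^2} +
   \sum_i \frac{A_i \tau_i'}{1+(\omega\tau_i')^2}\right],
   \qquad \frac{1}{\tau_i'} = \frac{1}{\tau_c} + \frac{1}{\tau_i}. $$

The 2/5 normalisation lives in $J(\omega)$, so the internal correlation
function is unit-normalised — stated explicitly because conventions
differ. `calc_relaxation()` evaluates the standard dipolar + CSA
expressions for R~1~, R~2~ and NOE with configurable constants
($r_{NH} = 1.02$ Å, ^15^N CSA $= -172$ ppm, 600 MHz ^1^H by default; none
are universal, all are arguments). `tauc_from_r2r1()` inverts the
rigid-rotor R~2~/R~1~ ratio per residue by root bisection and returns a
10%-trimmed mean, mimicking the usual exclusion of flexible and
exchange-broadened residues; ratios outside the attainable rigid-rotor
range are excluded with a message. Open- and closed-state rates are
combined by state population with `population_weighted_rates()`; R~1~ and
R~2~ average rate-wise, while the NOE is combined through the underlying
cross-relaxation rate $\sigma = (\mathrm{NOE}-1) R_1 \gamma_N/\gamma_H$,
because a quotient of rates must not be averaged directly.

Fitting experimental relaxation data to model-free parameters and
anisotropic diffusion are out of scope: the workflow back-calculates rates
from trajectory-derived models for comparison with experiment, not the
reverse.

## Gate dynamics

### Digitisation and transition counting

Gate distance trajectories (Cα–Cα distance between the active-site
cysteine and the central gate residue) are thresholded at 12 Å — the
conventional open/closed cutoff for this system — by `digitize_gate()`.
The default is faithful frame-wise thresholding (`min_dwell = 1`). Real
trajectories and the synthetic emission model both place distance noise
near the cutoff, which creates spurious single-frame recrossings; the
`min_dwell` option merges interior segments shorter than the given number
of frames into the flanking state, and the merge operates in run-length
space so it costs seconds even on multi-million-frame trajectories. With
the default emission model (means 7 Å and 14 Å, sd 1 Å, chosen to emulate
the observed ~6–8 Å closed and ~12–16 Å open distance bands)
`min_dwell = 3` removes over 90% of noise-induced crossings while leaving
true dwells (thousands of frames) untouched, which the tests verify
against the hidden state.

`transition_rates()` divides the number of exits from each state by the
total time resident in that state. A state never exited in a finite
trajectory yields the one-sided bound $k < 1/t_\mathrm{state}$, flagged
`upper_bound`, never an error — a µs-scale trajectory with no opening
events is informative, not broken.

### Eyring conversion

Rates convert to activation free energies with
$\Delta G^\ddagger = -RT\ln(k h/k_B T)$, i.e. transition-state theory with
transmission coefficient 1 and prefactor $k_B T/h \approx 6.2\times
10^{12}$ s^-1^ at 298 K. The true prefactor for a conformational change in
solution is not knowable from transition counts alone, so this is a
reporting convention, not a physical claim; it is self-consistent here —
a ~9 kcal/mol barrier corresponds to ~10^6^ s^-1^, i.e. a handful of
events per microsecond of trajectory, matching the sparse-transition
regime the method addresses — and the prefactor is an argument for anyone
preferring another convention. Closing barriers use the time-in-open
normalisation symmetric to opening.

### Steered-work free energy profiles

From an ensemble of work curves $W_i(x)$ recorded against the pulling
coordinate, `pmf_from_work()` applies the second-order cumulant expansion
of the Jarzynski equality,

$$ \Delta G(x) = \langle W(x)\rangle - \tfrac{\beta}{2}\,
   \mathrm{Var}\,W(x), $$

shifts the profile to zero at the start, and reports the maximum as the
barrier with a seeded bootstrap (1000 resamples over runs) confidence
interval. Runs on different grids are linearly interpolated onto their
common overlap; disjoint ranges are an error. The expansion is exact for
Gaussian work distributions and biased otherwise, which is why the
matching generator `sim_work_ensemble()` draws
$W_i(x) \sim N(G(x) + \beta\sigma_w^2/2,\ \sigma_w^2)$: under this
construction the estimator is exactly unbiased, so estimator tests
separate statistical error from expansion bias. Integrating work from
force traces is upstream and out of scope.

## The synthetic-data generators

Every generator takes an explicit seed, draws from a private RNG stream
(the global random state is untouched), and is byte-reproducible. Default
conditions mirror the study design: six titration points at 0, 200, 400,
560, 790, 1600 µM ligand against 417–428 µM protein; lysine series within
10–75 mM; chain-synthesis initial conditions of 8 µM thioester and 100 µM
Ub; 150 steered-work runs over a 10 Å pulling coordinate; gate emission
bands at 7/14 Å with 1 Å noise. Assay noise defaults to 2% of signal
amplitude — the fluorescence protocols do not state their noise levels, so
this is a package choice, exposed as `noise_sd` everywhere.

What the generators deliberately idealise: kinetic noise is Gaussian,
homoscedastic and uncorrelated (real gel densitometry has correlated,
signal-dependent errors); lineshape series share exact state shifts and
R~2~ across points (no temperature drift or weak secondary binding);
within-state gate distances are white about the state mean (real
trajectories have ~ps autocorrelation, which matters little here because
rate estimation uses dwell counts, not distance shape); work-curve noise
is independent across positions, whereas real pulling work accumulates.
Passing round-trip tests therefore demonstrates the correctness and
calibration of the estimators under the stated models — not robustness to
every pathology of real data.

## Numerical choices and degenerate inputs

* ODE integration: `lsoda`, rtol 10^-8^, atol 10^-12^ M; integrator
  failures raise errors with step diagnostics rather than returning
  partial traces.
* All nonlinear fits use multi-start Levenberg-Marquardt with rate-like
  parameters in log space; every fit object carries a `flag` field that is
  `NA` only for a clean fit.
* Lineshape grids default to 512 points spanning the two state shifts with
  a margin of 10 linewidths; integrated intensity is normalised by the
  trapezoid rule on the actual grid.
* `fit_correlation()` orders the two recovered time scales
  ($\tau_1 \le \tau_2$) and enforces amplitude bounds through the
  parameterisation $A_2 = 1 - A_\infty - A_1$ plus a penalty residual.
* Degenerate inputs (constant traces, flat product curves, zero-transition
  trajectories, all-equal CSPs) return flagged or bounded results; genuine
  contract violations (missing columns, negative concentrations,
  mismatched array lengths) are errors raised before any computation.

## Problem sizes

The test suite and the acceptance script size their simulations for desk
hardware as a package design choice: chain-synthesis fits use 60-point
hourly progress curves; the transition-counting round trip simulates
~120 expected opening events (~1.2 million frames at 100 ps); work
ensembles use the full 150 runs; the correlation-function oracle
integrates over 40 overall-tumbling times with a Simpson rule resolving
100 points per oscillation period. These sizes put Monte-Carlo error well
inside the tolerances being asserted (e.g. RT/sqrt(120) ≈ 0.05 kcal/mol
for the barrier round trip against a 0.3 kcal/mol tolerance).

## Known limitations

* The chain-synthesis model fixes the acceptor-binding rates to the
  values measured for the unconjugated enzyme; if thioester charging
  substantially changed UBA-domain affinity, $k_{Ub_2}$ estimates would
  absorb that error.
* The two-site lineshape model cannot represent a third exchanging state;
  visible multi-state behaviour should be fit per-pair or excluded.
* Eyring barriers inherit the prefactor convention; only barrier
  *differences* between variants are convention-free.
* The cumulant PMF estimator is second-order: for strongly non-Gaussian
  work distributions (fast pulling, rare slips) it underestimates
  barriers, consistent with steered estimates sitting below
  transition-counting estimates.
* No hidden-Markov state assignment is provided; digitisation is
  threshold-based by design, matching the analysis it reproduces.
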