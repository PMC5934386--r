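# Seeded generators for every input class the analysis stages consume.
# Each generator reproduces the statistical structure the corresponding fit
# assumes, so noiseless output is an exact inverse of the fit and noisy
# output has known ground truth. All randomness is drawn from a private
# RNG stream initialised from an explicit `seed`; no generator touches the
# global random state.

.check_noise <- function(noise_sd, seed) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (noise_sd > 0 && is.null(seed)) {
    abort("a `seed` is required whenever `noise_sd` > 0")
  }
}

#' Simulate an exponential kinetic trace
#'
#' Generates a fluorescence-style build-up or decay curve
#' `offset + amplitude * (1 - exp(-rate * t))` (rise) or
#' `offset + amplitude * exp(-rate * t)` (decay), with optional pointwise
#' Gaussian noise of standard deviation `noise_sd * amplitude`. This is the
#' data model behind two-parameter exponential fits of thioester
#' conjugation, hydrolysis and lysine aminolysis assays.
#'
#' @param times Sampling times in seconds, sorted ascending.
#' @param rate First-order rate constant in s^-1 (> 0).
#' @param amplitude Signal amplitude, arbitrary units.
#' @param offset Baseline offset, arbitrary units.
#' @param mode `"rise"` (build-up) or `"decay"`.
#' @param noise_sd Gaussian noise level as a fraction of `amplitude`.
#' @param seed Integer seed; required when `noise_sd > 0`.
#' @param species Label attached to the trace (e.g. `"thioester"`, `"Ub"`).
#' @return A tibble with columns `time_s`, `intensity`, `species`.
#' @examples
#' tr <- sim_exponential_trace(seq(0, 600, by = 30), rate = 0.19 / 60,
#'                             mode = "decay")
#' @export
sim_exponential_trace <- function(times, rate, amplitude = 1, offset = 0,
                                  mode = c("decay", "rise"),
                                  noise_sd = 0, seed = NULL,
                                  species = "thioester") {
  mode <- match.arg(mode)
  if (rate <= 0) abort("`rate` must be > 0")
  if (is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing")
  }
  .check_noise(noise_sd, seed)
  mean_y <- if (mode == "rise") {
    offset + amplitude * (1 - exp(-rate * times))
  } else {
    offset + amplitude * exp(-rate * times)
  }
  y <- .with_seed(seed, mean_y + rnorm(length(times), 0, noise_sd * amplitude))
  tibble(time_s = as.numeric(times), intensity = y, species = species)
}

#' Simulate observed aminolysis rates versus lysine concentration
#'
#' Observed aminolysis rate constants follow the quadratic rate law in the
#' neutral-lysine concentration,
#' `k_obs = kcat1 * [lys0] + kcat2 * [lys0]^2`, where `[lys0]` is the
#' neutral-side-chain fraction of total lysine given by
#' Henderson-Hasselbalch (see [neutral_lysine()]). Relative Gaussian noise
#' can be added to each `k_obs`.
#'
#' @param lys_totals Total lysine concentrations in molar (at least two).
#' @param kcat1 First-order catalytic constant, M^-1 s^-1.
#' @param kcat2 Second-order catalytic constant, M^-2 s^-1.
#' @param pH,pKa Solution pH and lysine side-chain pKa.
#' @param noise_sd Relative noise on each rate.
#' @param seed Integer seed; required when `noise_sd > 0`.
#' @return A tibble with columns `lys_total`, `lys_neutral`, `k_obs` (s^-1).
#' @export
sim_aminolysis_rates <- function(lys_totals, kcat1, kcat2,
                                 pH = 8.0, pKa = 10.54,
                                 noise_sd = 0, seed = NULL) {
  if (length(lys_totals) < 2) abort("need at least two lysine concentrations")
  .check_noise(noise_sd, seed)
  lys0 <- neutral_lysine(lys_totals, pH = pH, pKa = pKa)
  k_obs <- kcat1 * lys0 + kcat2 * lys0^2
  k_obs <- .with_seed(seed, k_obs * (1 + rnorm(length(k_obs), 0, noise_sd)))
  tibble(lys_total = as.numeric(lys_totals), lys_neutral = lys0, k_obs = k_obs)
}

#' Simulate di-ubiquitin chain-synthesis progress curves
#'
#' Integrates the six-species chain-synthesis ODE model (see
#' [chain_model()] and [simulate_chain_synthesis()]) and optionally adds
#' Gaussian noise scaled to each species' dynamic range.
#'
#' @param model A [chain_model()] object.
#' @param times Output times in seconds.
#' @param noise_sd Noise as a fraction of each species' amplitude
#'   (max - min of its noiseless trace).
#' @param seed Integer seed; required when `noise_sd > 0`.
#' @return A long tibble with columns `time_s`, `species`, `conc_M`.
#' @export
sim_chain_traces <- function(model, times, noise_sd = 0, seed = NULL) {
  .check_noise(noise_sd, seed)
  out <- simulate_chain_synthesis(model, times)
  if (noise_sd > 0) {
    out <- .with_seed(seed, {
      out |>
        dplyr::group_by(.data$species) |>
        dplyr::mutate(
          conc_M = .data$conc_M +
            rnorm(dplyr::n(), 0, noise_sd * max(diff(range(.data$conc_M)),
                                                .Machine$double.eps))
        ) |>
        dplyr::ungroup()
    })
  }
  out
}

#' Simulate a chemical-shift-perturbation titration
#'
#' Generates per-residue combined amide CSPs across a ligand titration from
#' a 1:1 binding model with ligand depletion: at each point the bound
#' protein fraction is computed from the exact quadratic mass balance and
#' each residue's CSP is `dd_max * fraction_bound`. Each residue is also
#' assigned a fixed direction in the (1H, 15N) shift plane so that the
#' component columns recombine to the stated CSP under the 1/5 nitrogen
#' scaling.
#'
#' @param kd Dissociation constant in molar.
#' @param dd_max Named numeric vector of per-residue saturating CSPs (ppm);
#'   names are residue identifiers.
#' @param ligand_totals,protein_totals Total ligand and protein
#'   concentrations in molar, one per titration point (equal length; first
#'   ligand point is typically 0, the reference).
#' @param noise_sd Absolute Gaussian noise on each CSP (ppm).
#' @param seed Integer seed; required when `noise_sd > 0`.
#' @return A tibble with columns `residue`, `point`, `ligand_total_M`,
#'   `protein_total_M`, `dd_hn_ppm`, `dd_n_ppm`, `dd_ppm`.
#' @export
sim_csp_titration <- function(kd, dd_max,
                              ligand_totals = c(0, 200, 400, 560, 790, 1600) * 1e-6,
                              protein_totals = c(417, 420, 421, 424, 424, 428) * 1e-6,
                              noise_sd = 0, seed = NULL) {
  stopifnot(kd > 0, all(dd_max >= 0))
  if (length(ligand_totals) != length(protein_totals)) {
    abort("`ligand_totals` and `protein_totals` must have equal length")
  }
  .check_noise(noise_sd, seed)
  if (is.null(names(dd_max))) names(dd_max) <- paste0("R", seq_along(dd_max))

  fb <- fraction_bound(ligand_totals, protein_totals, kd)
  # fixed per-residue direction in the (1H, 15N) plane, deterministic
  theta <- (seq_along(dd_max) %% 7 + 1) * pi / 16

  grid <- tidyr::expand_grid(
    residue = names(dd_max),
    point = seq_along(ligand_totals)
  ) |>
    dplyr::mutate(
      ligand_total_M = ligand_totals[.data$point],
      protein_total_M = protein_totals[.data$point],
      dd_ppm = dd_max[.data$residue] * fb[.data$point],
      dd_hn_ppm = .data$dd_ppm * cos(theta[match(.data$residue, names(dd_max))]),
      dd_n_ppm = 5 * .data$dd_ppm * sin(theta[match(.data$residue, names(dd_max))])
    )
  if (noise_sd > 0) {
    grid <- .with_seed(seed, dplyr::mutate(
      grid,
      dd_ppm = pmax(0, .data$dd_ppm + rnorm(dplyr::n(), 0, noise_sd))
    ))
  }
  dplyr::select(grid, "residue", "point", "ligand_total_M", "protein_total_M",
                "dd_hn_ppm", "dd_n_ppm", "dd_ppm")
}

#' Simulate a titration series of two-site exchange lineshapes
#'
#' For each titration point the free-ligand concentration and bound
#' population follow from the 1:1 depletion mass balance at
#' `K_D = koff/kon`, and the 1D absorption spectrum is computed from the
#' Bloch-McConnell two-site exchange equations (see
#' [simulate_lineshape()]). Optional Gaussian noise is scaled to each
#' spectrum's maximum.
#'
#' @param kon,koff Association (M^-1 s^-1) and dissociation (s^-1) rates.
#' @param shift_free_hz,shift_bound_hz Resonance frequencies of the free and
#'   bound states, Hz.
#' @param r2_free,r2_bound Transverse relaxation rates, s^-1.
#' @param protein_totals,ligand_totals Concentrations in molar, per point.
#' @param freq_hz Frequency grid (Hz); default 512 points spanning the two
#'   shifts with a margin.
#' @param noise_sd Noise as a fraction of each spectrum's peak intensity.
#' @param seed Integer seed; required when `noise_sd > 0`.
#' @return A tibble with columns `point`, `ligand_total_M`,
#'   `protein_total_M`, `freq_hz`, `intensity`.
#' @export
sim_titration_lineshapes <- function(kon, koff,
                                     shift_free_hz = 0, shift_bound_hz = 120,
                                     r2_free = 5, r2_bound = 5,
                                     protein_totals = c(417, 420, 421, 424, 424, 428) * 1e-6,
                                     ligand_totals = c(0, 200, 400, 560, 790, 1600) * 1e-6,
                                     freq_hz = NULL, noise_sd = 0, seed = NULL) {
  if (kon <= 0 || koff <= 0) abort("`kon` and `koff` must be > 0")
  if (any(protein_totals <= 0)) abort("protein concentrations must be > 0")
  if (length(ligand_totals) != length(protein_totals)) {
    abort("`ligand_totals` and `protein_totals` must have equal length")
  }
  .check_noise(noise_sd, seed)
  if (is.null(freq_hz)) {
    lo <- min(shift_free_hz, shift_bound_hz)
    hi <- max(shift_free_hz, shift_bound_hz)
    pad <- max(hi - lo, 50) * 0.75 + 10 * max(r2_free, r2_bound) / pi
    freq_hz <- seq(lo - pad, hi + pad, length.out = 512)
  }
  kd <- koff / kon
  out <- purrr::map_dfr(seq_along(ligand_totals), function(i) {
    sp <- simulate_lineshape(
      kon = kon, koff = koff,
      shift_free_hz = shift_free_hz, shift_bound_hz = shift_bound_hz,
      r2_free = r2_free, r2_bound = r2_bound,
      protein_total = protein_totals[i], ligand_total = ligand_totals[i],
      freq_hz = freq_hz
    )
    tibble(point = i, ligand_total_M = ligand_totals[i],
           protein_total_M = protein_totals[i],
           freq_hz = sp$freq_hz, intensity = sp$intensity)
  })
  if (noise_sd > 0) {
    out <- .with_seed(seed, {
      out |>
        dplyr::group_by(.data$point) |>
        dplyr::mutate(intensity = .data$intensity +
                        rnorm(dplyr::n(), 0, noise_sd * max(.data$intensity))) |>
        dplyr::ungroup()
    })
  }
  out
}

#' Simulate a two-state gate distance trajectory
#'
#' The hidden gate state follows a continuous-time two-state Markov chain
#' (exponential dwell times with rates `k_open` out of the closed state and
#' `k_close` out of the open state), sampled on a uniform frame grid of
#' spacing `dt_ps`. The emitted distance at each frame is the state mean
#' plus Gaussian noise. Defaults emulate the closed (~6-8 Angstrom) and
#' open (~12-16 Angstrom) distance bands of E2 active-site gates.
#'
#' @param k_open,k_close Opening and closing rates, s^-1 (> 0; `k_open = 0`
#'   is allowed and pins the chain in the closed state).
#' @param dt_ps Frame spacing in picoseconds.
#' @param duration_s Trajectory length in seconds.
#' @param closed_mean,open_mean State mean distances, Angstrom.
#' @param emission_sd Within-state distance noise, Angstrom.
#' @param seed Integer seed (required; the trajectory is stochastic).
#' @param start Initial state, `"closed"` or `"open"`.
#' @return A tibble with columns `time_ps`, `distance_A` and the hidden
#'   truth `state_true` (`"closed"`/`"open"`).
#' @export
sim_gate_trajectory <- function(k_open, k_close, dt_ps = 100,
                                duration_s = 1e-5,
                                closed_mean = 7, open_mean = 14,
                                emission_sd = 1, seed = NULL,
                                start = c("closed", "open")) {
  start <- match.arg(start)
  if (k_open < 0 || k_close < 0) abort("rates must be >= 0")
  if (is.null(seed)) abort("`seed` is required for trajectory simulation")
  dt_s <- dt_ps * 1e-12
  n_frames <- floor(duration_s / dt_s)
  if (n_frames < 2) abort("duration shorter than two frames")
  k_mean <- mean(c(k_open, k_close))
  if (k_mean > 0 && duration_s * k_mean < 10) {
    warn("trajectory shorter than ~10 expected dwells; rate estimates will be poor")
  }

  .with_seed(seed, {
    # alternate exponential dwells until the duration is covered
    state0 <- if (start == "closed") 0L else 1L
    dwell_end <- numeric(0)
    t_acc <- 0
    s <- state0
    repeat {
      rate_out <- if (s == 0L) k_open else k_close
      if (rate_out <= 0) { dwell_end <- c(dwell_end, Inf); break }
      t_acc <- t_acc + rexp(1, rate_out)
      dwell_end <- c(dwell_end, t_acc)
      s <- 1L - s
      if (t_acc > duration_s) break
    }
    frame_times <- (seq_len(n_frames) - 1) * dt_s
    seg <- findInterval(frame_times, dwell_end) # 0-based segment index
    states <- (state0 + seg) %% 2L
    dist <- ifelse(states == 1L, open_mean, closed_mean) +
      rnorm(n_frames, 0, emission_sd)
    tibble(
      time_ps = frame_times * 1e12,
      distance_A = dist,
      state_true = ifelse(states == 1L, "open", "closed")
    )
  })
}

#' Gaussian-bump free-energy profile
#'
#' Convenience constructor for a smooth potential of mean force with a
#' single barrier: `G(x) = barrier * exp(-(x - center)^2 / (2 * width^2))`,
#' shifted so the profile starts at zero.
#'
#' @param positions Pulling-coordinate grid, Angstrom (monotone increasing).
#' @param barrier Barrier height, kcal/mol.
#' @param center,width Barrier position and Gaussian width, Angstrom.
#' @return A tibble with columns `position_A`, `g_kcal`.
#' @export
pmf_gaussian_barrier <- function(positions = seq(0, 10, by = 0.1),
                                 barrier = 6.1, center = 6, width = 1.5) {
  if (is.unsorted(positions, strictly = TRUE)) {
    abort("`positions` must be strictly increasing")
  }
  g <- barrier * exp(-(positions - center)^2 / (2 * width^2))
  g <- g - g[1]
  # rescale so the profile maximum relative to the start is exactly `barrier`
  if (max(g) > 0) g <- g * barrier / max(g)
  tibble(position_A = as.numeric(positions), g_kcal = g)
}

#' Simulate a Jarzynski-consistent steered-work ensemble
#'
#' Draws `n_runs` work curves over the pulling coordinate with
#' `W_i(x) ~ Normal(G(x) + beta * sigma_w(x)^2 / 2, sigma_w(x)^2)`,
#' where `beta = 1/RT`. Under this construction the second-order cumulant
#' estimator `<W> - (beta/2) Var(W)` is unbiased for `G(x)`, so estimator
#' bias can be tested cleanly.
#'
#' @param pmf A data frame with columns `position_A`, `g_kcal` (e.g. from
#'   [pmf_gaussian_barrier()]).
#' @param sigma_w Work standard deviation, kcal/mol; scalar or one value per
#'   grid position.
#' @param n_runs Number of pulling runs (>= 2).
#' @param temperature Temperature in kelvin.
#' @param seed Integer seed (required when `sigma_w > 0`).
#' @return A tibble with columns `position_A`, `run`, `work_kcal`.
#' @export
sim_work_ensemble <- function(pmf, sigma_w = 1, n_runs = 150,
                              temperature = 298, seed = NULL) {
  .require_cols(pmf, c("position_A", "g_kcal"), "`pmf`")
  if (n_runs < 2) abort("`n_runs` must be >= 2")
  if (any(sigma_w < 0)) abort("`sigma_w` must be >= 0")
  if (is.unsorted(pmf$position_A, strictly = TRUE)) {
    abort("`position_A` must be strictly increasing")
  }
  if (any(sigma_w > 0) && is.null(seed)) abort("`seed` required when sigma_w > 0")
  npos <- nrow(pmf)
  sig <- rep_len(sigma_w, npos)
  beta <- 1 / .rt_kcal(temperature)
  mu <- pmf$g_kcal + beta * sig^2 / 2
  .with_seed(seed, {
    purrr::map_dfr(seq_len(n_runs), function(r) {
      tibble(position_A = pmf$position_A, run = r,
             work_kcal = mu + rnorm(npos, 0, sig))
    })
  })
}
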