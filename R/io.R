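# Tabular readers/writers and a config-driven pipeline entry point.
# All tables are plain CSV; results are written as JSON with a provenance
# block (stage, parameters, seed) so runs are reproducible.

.read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- utils::read.csv(path, check.names = FALSE)
  .require_cols(df, required, what)
  bad <- which(!stats::complete.cases(df[required]))
  if (length(bad) > 0) {
    abort(sprintf("%s: malformed value(s) at data row(s) %s of %s",
                  what, paste(utils::head(bad, 5), collapse = ", "), path))
  }
  as_tibble(df)
}

#' Read a kinetic trace CSV
#'
#' Expects columns `time_s` (or `time_min` with `time_unit = "min"`),
#' `intensity` and optionally `species`. Times are converted to seconds
#' internally; a file with a `time_min` column read without the flag is an
#' error rather than a silent unit mix-up.
#'
#' @param path CSV path.
#' @param time_unit `"s"` or `"min"`.
#' @return A tibble with columns `time_s`, `intensity`, `species`.
#' @export
read_kinetic_trace <- function(path, time_unit = c("s", "min")) {
  time_unit <- match.arg(time_unit)
  df <- utils::read.csv(path, check.names = FALSE)
  tcol <- paste0("time_", time_unit)
  if (!tcol %in% names(df)) {
    have <- grep("^time_", names(df), value = TRUE)
    abort(sprintf("expected column `%s`; file has: %s (set `time_unit` accordingly)",
                  tcol, paste(have, collapse = ", ")))
  }
  .require_cols(df, c(tcol, "intensity"), "kinetic trace")
  tibble(
    time_s = if (time_unit == "min") df[[tcol]] * 60 else df[[tcol]],
    intensity = df$intensity,
    species = if ("species" %in% names(df)) df$species else "unknown"
  )
}

#' Read a titration lineshape CSV
#'
#' Expects columns `point`, `ligand_total_M`, `protein_total_M`, `freq_hz`,
#' `intensity`, the layout written by [sim_titration_lineshapes()].
#'
#' @param path CSV path.
#' @return A tibble suitable for [fit_exchange()].
#' @export
read_lineshapes <- function(path) {
  .read_csv_checked(path, c("point", "ligand_total_M", "protein_total_M",
                            "freq_hz", "intensity"), "lineshape table")
}

#' Read a gate distance trajectory CSV
#'
#' Expects columns `time_ps`, `distance_A`.
#'
#' @param path CSV path.
#' @return A tibble suitable for [digitize_gate()].
#' @export
read_gate_trajectory <- function(path) {
  .read_csv_checked(path, c("time_ps", "distance_A"), "gate trajectory")
}

#' Read a steered-work ensemble CSV
#'
#' Expects columns `position_A`, `run` (or `run_id`), `work_kcal` (or
#' `work_kcal_mol`).
#'
#' @param path CSV path.
#' @return A tibble suitable for [pmf_from_work()].
#' @export
read_work_ensemble <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if ("run_id" %in% names(df) && !"run" %in% names(df)) df$run <- df$run_id
  if ("work_kcal_mol" %in% names(df) && !"work_kcal" %in% names(df)) {
    df$work_kcal <- df$work_kcal_mol
  }
  .require_cols(df, c("position_A", "run", "work_kcal"), "work ensemble")
  as_tibble(df[c("position_A", "run", "work_kcal")])
}

#' Read a per-residue relaxation table CSV
#'
#' Expects columns `residue`, `r1_s`, `r2_s` and optionally `noe`,
#' `field_mhz`.
#'
#' @param path CSV path.
#' @return A tibble suitable for [tauc_from_r2r1()].
#' @export
read_relaxation_table <- function(path) {
  .read_csv_checked(path, c("residue", "r1_s", "r2_s"), "relaxation table")
}

#' Write an analysis result as JSON with provenance
#'
#' Serialises a result list (or fit object, via [tidy()]/[glance()] if
#' available) together with a provenance block recording the stage name,
#' parameters, seed and package version.
#'
#' @param result A list of numbers/tibbles to serialise.
#' @param path Output JSON path.
#' @param stage Stage name recorded in the provenance block.
#' @param params Parameter list recorded in the provenance block.
#' @param seed Seed recorded in the provenance block.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(result, path, stage = "analysis",
                               params = list(), seed = NULL) {
  payload <- list(
    provenance = list(
      stage = stage, params = params, seed = seed,
      package = "gatekin",
      version = as.character(utils::packageVersion("gatekin"))
    ),
    result = result
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Run an analysis stage from a configuration
#'
#' Dispatches one named analysis stage with validated parameters, reading
#' inputs from CSV and writing a JSON result with provenance. The
#' configuration is a named list (or the path of a YAML file holding one)
#' with elements `stage`, `input` (path, where applicable), `params`
#' (stage-specific overrides), `seed` and `out` (output JSON path,
#' optional). Available stages: `simulate_chain`, `fit_exponential`,
#' `fit_aminolysis`, `fit_chain`, `fit_titration`, `fit_lineshape`,
#' `gate_analyze`, `smd_pmf`, `tauc`.
#'
#' @param config A named list or YAML file path.
#' @return The stage result (also written to `config$out` when given).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$stage)) abort("config must name a `stage`")
  params <- config$params %||% list()
  seed <- config$seed
  num <- function(x, what) {
    if (is.null(x) || !is.numeric(x) || any(!is.finite(x)) ) {
      abort(paste0("config parameter `", what, "` must be numeric and finite"))
    }
    x
  }

  result <- switch(
    config$stage,
    simulate_chain = {
      init <- unlist(params$init)
      if (any(init < 0)) abort("initial concentrations must be >= 0")
      m <- chain_model(num(params$kon, "kon"), num(params$koff, "koff"),
                       num(params$k_h2o, "k_h2o"), num(params$k_ub2, "k_ub2"),
                       init = init)
      sim_chain_traces(m, num(params$times, "times"),
                       noise_sd = params$noise_sd %||% 0, seed = seed)
    },
    fit_exponential = {
      tr <- read_kinetic_trace(config$input,
                               time_unit = params$time_unit %||% "s")
      fit_exponential(tr, mode = params$mode %||% "auto")
    },
    fit_aminolysis = {
      df <- .read_csv_checked(config$input, c("lys_total", "k_obs"),
                              "aminolysis series")
      fit_aminolysis(df, pH = params$pH %||% 8.0, pKa = params$pKa %||% 10.54)
    },
    fit_chain = {
      # validate the kinetic parameters before any file access or compute
      init <- unlist(params$init)
      if (any(init < 0)) abort("initial concentrations must be >= 0")
      m <- chain_model(num(params$kon, "kon"), num(params$koff, "koff"),
                       num(params$k_h2o, "k_h2o"), k_ub2 = 0, init = init)
      df <- .read_csv_checked(config$input, c("time_s", "conc_M"), "Ub2 trace")
      fit_kub2(df, m)
    },
    fit_titration = {
      df <- .read_csv_checked(config$input,
                              c("residue", "ligand_total_M",
                                "protein_total_M", "dd_ppm"), "titration")
      fit_kd(df, mode = params$mode %||% "global")
    },
    fit_lineshape = {
      fit_exchange(read_lineshapes(config$input),
                   shared_r2 = params$shared_r2 %||% TRUE)
    },
    gate_analyze = {
      traj <- read_gate_trajectory(config$input)
      seqs <- digitize_gate(traj, cutoff = params$cutoff %||% 12,
                            min_dwell = params$min_dwell %||% 1)
      list(rates = transition_rates(seqs),
           barriers = gate_barriers(seqs,
                                    temperature = params$temperature %||% 298))
    },
    smd_pmf = {
      pmf_from_work(read_work_ensemble(config$input),
                    temperature = params$temperature %||% 298,
                    n_boot = params$n_boot %||% 1000, seed = seed)
    },
    tauc = {
      tauc_from_r2r1(read_relaxation_table(config$input),
                     field_mhz = params$field_mhz %||% 600)
    },
    abort(paste0("unknown stage: ", config$stage))
  )

  if (!is.null(config$out)) {
    serialisable <- .result_to_list(result)
    write_results_json(serialisable, config$out, stage = config$stage,
                       params = params, seed = seed)
  }
  result
}

.result_to_list <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (inherits(x, "chain_model")) {
    return(list(kon = x$kon, koff = x$koff, k_h2o = x$k_h2o,
                k_ub2 = x$k_ub2, init = as.list(x$init)))
  }
  if (inherits(x, c("exp_fit", "aminolysis_fit", "kd_fit", "exchange_fit",
                    "kub2_fit", "pmf_estimate", "gate_rates", "corr_fit"))) {
    keep <- x[!vapply(x, function(e) is.function(e) || inherits(e, "lm"),
                      logical(1))]
    return(purrr::map(keep, .result_to_list))
  }
  if (is.list(x)) return(purrr::map(x, .result_to_list))
  x
}
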