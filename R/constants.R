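# Physical constants (SI unless noted). Internal units are seconds and molar
# throughout; kcal/mol for free energies; Hz for lineshape frequency axes.

.const <- list(
  kB       = 1.380649e-23,       # J/K
  h        = 6.62607015e-34,     # J s
  hbar     = 1.054571817e-34,    # J s
  R_kcal   = 1.987204259e-3,     # kcal mol^-1 K^-1
  gamma_h  = 2.6752218744e8,     # 1H gyromagnetic ratio, rad s^-1 T^-1
  gamma_n  = -2.7126189e7,       # 15N gyromagnetic ratio, rad s^-1 T^-1
  mu0_4pi  = 1e-7                # T m A^-1
)

#' Eyring prefactor kB*T/h
#'
#' Attempt frequency of transition-state theory at temperature `temperature`,
#' with unit transmission coefficient.
#'
#' @param temperature Temperature in kelvin.
#' @return Rate prefactor in s^-1.
#' @examples
#' eyring_prefactor(298) # ~6.21e12 s^-1
#' @export
eyring_prefactor <- function(temperature = 298) {
  stopifnot(temperature > 0)
  .const$kB * temperature / .const$h
}

# thermal energy RT in kcal/mol
.rt_kcal <- function(temperature) .const$R_kcal * temperature

# run expr with a private RNG stream; never touches the global seed state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

.require_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
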