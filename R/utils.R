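# Physical constants (SI), combined where only the combination is used.
.const <- list(
  avogadro = 6.02214076e23,           # mol^-1
  # e^2 / (4 pi eps0 kB) in Angstrom * Kelvin; divide by (eps_r * T) to get
  # the Bjerrum length in Angstrom. CODATA 2018 constants.
  bjerrum_AK = 1.602176634e-19^2 /
    (4 * pi * 8.8541878128e-12 * 1.380649e-23) * 1e10
)

#' Bjerrum length in Angstrom
#' @param temperature Kelvin
#' @param relative_permittivity dimensionless
#' @keywords internal
#' @noRd
bjerrum_length <- function(temperature, relative_permittivity) {
  .const$bjerrum_AK / (relative_permittivity * temperature)
}

#' Inverse Debye screening length (kappa) in 1/Angstrom
#'
#' kappa^2 = 8 pi l_B n_I with n_I the ionic strength converted to a number
#' density in Angstrom^-3 (1:1 electrolyte convention).
#' @keywords internal
#' @noRd
debye_kappa <- function(ionic_strength, temperature, relative_permittivity) {
  lb <- bjerrum_length(temperature, relative_permittivity)
  n_dens <- ionic_strength * .const$avogadro * 1e-27  # mol/L -> per Angstrom^3
  sqrt(8 * pi * lb * n_dens)
}

# Evaluate expr with the global RNG seeded to `seed`, restoring the previous
# RNG state afterwards so library code never perturbs a user's stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
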