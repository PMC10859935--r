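# Three-term pair interaction energy between rigid bodies:
# hard-core steric clash + 12-6 Lennard-Jones attraction + Debye-Hueckel
# screened electrostatics. All energies are carried in units of kB*T.

#' Energy model parameters
#'
#' Bundles the parameters of the three-term pair energy model. The steric
#' term is infinite when two atoms approach closer than
#' `clash_factor * (r_a + r_b)` and zero otherwise. In clash-free
#' configurations the nonpolar term is a 12-6 Lennard-Jones potential with
#' contact parameter `sigma = r_a + r_b` and well depth `lj_well_depth`
#' (minimum of `-lj_well_depth` at separation `sigma`), and the
#' electrostatic term is the Debye-Hueckel screened Coulomb interaction
#' `q_a q_b l_B exp(-kappa d) / d` with the Bjerrum length `l_B` and the
#' inverse screening length `kappa` derived from temperature, relative
#' permittivity and ionic strength.
#'
#' @param temperature absolute temperature in K (default 298).
#' @param ionic_strength ionic strength in mol/L (default 0.175).
#' @param relative_permittivity solvent dielectric constant (default 78.5).
#' @param clash_factor dimensionless hard-core scaling eta in (0, 1]
#'   (default 0.8): atoms clash below `eta * (r_a + r_b)`.
#' @param lj_well_depth Lennard-Jones well depth per atom pair in kBT
#'   (default 0.3).
#' @param energy_cap finite-energy cap in kBT (default 20) applied when
#'   Boltzmann factors are formed; near the clash boundary a capped energy
#'   contributes a Mayer factor of essentially -1, matching the steric
#'   limit.
#' @param r_cut interaction truncation radius in Angstrom used by grid
#'   scans; `NULL` (default) chooses `max(3 Debye lengths, 16)` at scan
#'   time. Pairwise energies beyond `r_cut` are treated as zero by the
#'   scanning machinery (not by [pair_potential()], which is exact).
#' @return list of class `energy_params` with derived fields `bjerrum`
#'   (Angstrom) and `kappa` (1/Angstrom).
#' @export
energy_params <- function(temperature = 298, ionic_strength = 0.175,
                          relative_permittivity = 78.5, clash_factor = 0.8,
                          lj_well_depth = 0.3, energy_cap = 20,
                          r_cut = NULL) {
  if (temperature <= 0) stopf("temperature must be > 0")
  if (ionic_strength < 0) stopf("ionic_strength must be >= 0")
  if (clash_factor <= 0 || clash_factor > 1)
    stopf("clash_factor must be in (0, 1]")
  p <- list(temperature = temperature, ionic_strength = ionic_strength,
            relative_permittivity = relative_permittivity,
            clash_factor = clash_factor, lj_well_depth = lj_well_depth,
            energy_cap = energy_cap, r_cut = r_cut)
  p$bjerrum <- bjerrum_length(temperature, relative_permittivity)
  p$kappa <- debye_kappa(ionic_strength, temperature, relative_permittivity)
  class(p) <- "energy_params"
  p
}

#' @export
print.energy_params <- function(x, ...) {
  cat(sprintf(
    paste0("<energy_params> T = %g K, I = %g M, eps_r = %g\n",
           "  l_B = %.3f A, 1/kappa = %s A, eta = %g, ",
           "LJ depth = %g kBT, cap = %g kBT\n"),
    x$temperature, x$ionic_strength, x$relative_permittivity, x$bjerrum,
    if (x$kappa > 0) sprintf("%.2f", 1 / x$kappa) else "Inf",
    x$clash_factor, x$lj_well_depth, x$energy_cap))
  invisible(x)
}

# Vectorized pairwise energy terms at distances d (Angstrom) for charge
# products qprod (e^2) and contact parameters sigma (Angstrom).
# Returns list(clash, nonpolar, electrostatic); terms beyond r_cut are 0.
# Distances of exactly 0 are always inside the clash core (radii > 0), so
# the finite terms there are set to 0 rather than NaN.
pair_terms <- function(d, qprod, sigma, p, r_cut = Inf) {
  clash <- d < p$clash_factor * sigma
  zero <- d <= 0
  out_of_range <- d > r_cut
  dd <- ifelse(zero, 1, d)
  sr6 <- (sigma / dd)^6
  nonpolar <- p$lj_well_depth * (sr6^2 - 2 * sr6)
  electrostatic <- qprod * p$bjerrum * exp(-p$kappa * dd) / dd
  nonpolar[zero | out_of_range] <- 0
  electrostatic[zero | out_of_range] <- 0
  list(clash = clash, nonpolar = nonpolar, electrostatic = electrostatic)
}

#' Pair interaction energy of two atoms
#'
#' Evaluates the three-term pair energy for one atom pair at a given
#' center-center distance. See [energy_params()] for the functional forms.
#'
#' @param a,b atom records: lists or one-row data frames with fields
#'   `charge` (e) and `radius` (Angstrom).
#' @param distance center-center distance in Angstrom (> 0).
#' @param p an [energy_params()] object.
#' @return list of class `energy_components` with elements `steric`
#'   (0 or `Inf`), `nonpolar`, `electrostatic`, and `total` (all kBT);
#'   `total = nonpolar + electrostatic` when clash-free, `Inf` otherwise.
#' @export
pair_potential <- function(a, b, distance, p = energy_params()) {
  if (!is.finite(distance) || distance <= 0)
    stopf("distance must be a positive finite number")
  sigma <- a$radius + b$radius
  t <- pair_terms(distance, a$charge * b$charge, sigma, p)
  comps <- list(steric = if (t$clash) Inf else 0,
                nonpolar = t$nonpolar, electrostatic = t$electrostatic)
  comps$total <- if (t$clash) Inf else t$nonpolar + t$electrostatic
  class(comps) <- "energy_components"
  comps
}

#' @export
print.energy_components <- function(x, ...) {
  cat(sprintf("<energy_components> steric %s, LJ %.4g, elec %.4g, total %s kBT\n",
              if (is.infinite(x$steric)) "Inf" else "0",
              x$nonpolar, x$electrostatic,
              if (is.infinite(x$total)) "Inf" else sprintf("%.4g", x$total)))
  invisible(x)
}

#' Interaction energy of one relative configuration of two rigid bodies
#'
#' Sums the pair potential over all cross pairs of atoms after applying
#' `rotation` to body `B` (about its centroid frame origin, i.e. its file
#' coordinates) and translating it by `displacement`. Any clashing pair
#' makes the total infinite.
#'
#' @param A,B `rigid_structure` objects.
#' @param rotation 3x3 rotation matrix applied to B's coordinates.
#' @param displacement length-3 translation in Angstrom applied after
#'   rotation.
#' @param p an [energy_params()] object.
#' @param charges_A,charges_B optional per-atom charge vectors overriding
#'   the file charges (used for protonation microstates).
#' @return an `energy_components` list as in [pair_potential()].
#' @export
pose_energy <- function(A, B, rotation = diag(3), displacement = c(0, 0, 0),
                        p = energy_params(), charges_A = NULL,
                        charges_B = NULL) {
  xa <- coords(A)
  xb <- coords(B) %*% t(rotation)
  xb <- sweep(xb, 2, displacement, "+")
  qa <- charges_A %||% A$atoms$charge
  qb <- charges_B %||% B$atoms$charge
  ra <- A$atoms$radius
  rb <- B$atoms$radius
  na <- nrow(xa); nb <- nrow(xb)
  # all cross-pair distances
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d <- sqrt(pmax(d2, 0))
  sigma <- outer(ra, rb, "+")
  qprod <- outer(qa, qb)
  t <- pair_terms(as.vector(d), as.vector(qprod), as.vector(sigma), p)
  comps <- list(steric = if (any(t$clash)) Inf else 0,
                nonpolar = sum(t$nonpolar),
                electrostatic = sum(t$electrostatic))
  comps$total <- if (any(t$clash)) Inf else comps$nonpolar + comps$electrostatic
  class(comps) <- "energy_components"
  comps
}
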