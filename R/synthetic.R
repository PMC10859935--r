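# Synthetic fixtures: rigid toy bodies with patterned surface charges,
# sigmoidal titration curves, turbidity-onset curves, and feature tables
# generated from a known linear model on planted principal components.
# Every generator is pure given its arguments and seed.

# Fibonacci lattice: n quasi-uniform points on the unit sphere
.fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Generate a rigid toy body
#'
#' Builds small rigid structures with controlled surface-charge patterns,
#' suitable for exercising the full virial pipeline in seconds:
#' \describe{
#'   \item{`"sphere-shell"`}{atoms quasi-uniformly on a spherical shell,
#'     net charge spread uniformly — a nearly isotropic body.}
#'   \item{`"two-patch"`}{a shell with a positive polar cap and a negative
#'     polar cap (a surface-charge dipole), emulating the pairing of
#'     oppositely charged surface patches that drives weak
#'     self-association. The positive cap can be made titratable, in which
#'     case its atoms form a single histidine-like residue whose +1 charge
#'     switches on at low pH.}
#'   \item{`"linear-peptide"`}{one atom per residue along the z axis — a
#'     minimal extended peptide, e.g. an acidic SIM-like probe.}
#' }
#'
#' @param geometry one of `"sphere-shell"`, `"two-patch"`,
#'   `"linear-peptide"`.
#' @param n_atoms number of atoms (default 48; kept small so full virial
#'   runs stay fast).
#' @param body_radius shell radius in Angstrom (default 9) for the sphere
#'   geometries; residue spacing is 3.5 A for the peptide.
#' @param atom_radius per-atom radius in Angstrom (default 1.8).
#' @param net_charge total charge (e) for `"sphere-shell"` and
#'   `"linear-peptide"` (spread uniformly, exactly).
#' @param patch_charges length-2: total charge of the +z and -z polar caps
#'   for `"two-patch"` (default `c(1, -1)`).
#' @param titratable_patch for `"two-patch"`: if `TRUE`, the +z cap is a
#'   neutral histidine-like titratable residue (its file charge is 0 and
#'   `patch_charges[1]` is ignored); protonation adds +1.
#' @param atoms_per_residue grouping of shell atoms into residues
#'   (default 4), so per-residue decomposition is exercised.
#' @param first_residue_id starting residue id (default 1).
#' @param jitter_sd Gaussian positional jitter in Angstrom (default 0.1),
#'   drawn from `seed` so the body is reproducible.
#' @param seed integer seed.
#' @return a [rigid_structure()].
#' @export
make_toy_body <- function(geometry = c("sphere-shell", "two-patch",
                                       "linear-peptide"),
                          n_atoms = 48, body_radius = 9, atom_radius = 1.8,
                          net_charge = 0, patch_charges = c(1, -1),
                          titratable_patch = FALSE, atoms_per_residue = 4,
                          first_residue_id = 1L, jitter_sd = 0.1,
                          seed = 1L) {
  geometry <- match.arg(geometry)
  if (n_atoms < 2) stopf("need at least 2 atoms")
  jit <- with_local_seed(seed, matrix(stats::rnorm(3 * n_atoms, 0, jitter_sd),
                                      ncol = 3))
  if (geometry == "linear-peptide") {
    xyz <- cbind(0, 0, 3.5 * (seq_len(n_atoms) - 1)) + jit
    q <- rep(net_charge / n_atoms, n_atoms)
    atoms <- data.frame(
      atom_name = "CA", residue_name = "GLY",
      residue_id = first_residue_id + seq_len(n_atoms) - 1L, chain_id = "A",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      charge = q, radius = atom_radius)
    return(rigid_structure(atoms, conformation_tag = "other",
                           titratable_sites = data.frame(residue_id = integer(0),
                                                         pKa = numeric(0))))
  }

  xyz <- body_radius * .fib_sphere(n_atoms) + jit
  zhat <- .fib_sphere(n_atoms)[, 3]
  pos_cap <- zhat > 0.6
  neg_cap <- zhat < -0.6
  if (geometry == "two-patch" && (!any(pos_cap) || !any(neg_cap)))
    stopf("too few atoms to form both polar caps")
  q <- rep(0, n_atoms)
  if (geometry == "sphere-shell") {
    q <- rep(net_charge / n_atoms, n_atoms)
  } else {
    if (!titratable_patch) q[pos_cap] <- patch_charges[1] / sum(pos_cap)
    q[neg_cap] <- patch_charges[2] / sum(neg_cap)
  }

  # residues: the caps become dedicated residues; the rest is grouped
  # sequentially into residues of atoms_per_residue atoms
  rid <- integer(n_atoms)
  rname <- character(n_atoms)
  body_idx <- which(!pos_cap & !neg_cap)
  rid[body_idx] <- first_residue_id +
    (seq_along(body_idx) - 1L) %/% atoms_per_residue
  rname[body_idx] <- "GLY"
  next_id <- if (length(body_idx)) max(rid[body_idx]) + 1L else first_residue_id
  if (geometry == "two-patch") {
    rid[pos_cap] <- next_id
    rname[pos_cap] <- if (titratable_patch) "HIS" else "LYS"
    rid[neg_cap] <- next_id + 1L
    rname[neg_cap] <- "GLU"
  } else {
    rid[pos_cap] <- next_id; rname[pos_cap] <- "GLY"
    rid[neg_cap] <- next_id + 1L; rname[neg_cap] <- "GLY"
  }

  ord <- order(rid)
  atoms <- data.frame(
    atom_name = "CA", residue_name = rname[ord], residue_id = rid[ord],
    chain_id = "A", x = xyz[ord, 1], y = xyz[ord, 2], z = xyz[ord, 3],
    charge = q[ord], radius = atom_radius)
  ts <- if (geometry == "two-patch" && titratable_patch) {
    data.frame(residue_id = next_id, pKa = 6.3)
  } else data.frame(residue_id = integer(0), pKa = numeric(0))
  rigid_structure(atoms, conformation_tag = "other", titratable_sites = ts)
}

#' Generate a synthetic pH titration series
#'
#' Draws chemical shifts on the two-plateau Hill curve (see [fit_hill()])
#' with optional Gaussian noise; emulates an NMR pH titration over
#' pH 5.5-8.0.
#'
#' @param pKa,hill_n,shift_prot,shift_neutral curve parameters.
#' @param noise_sd Gaussian noise sd in ppm (0 = exactly on the curve).
#' @param pH pH sampling points (default the eight points 5.5-8.0 used in
#'   typical titration experiments).
#' @param seed integer seed.
#' @return a [titration_series()].
#' @export
make_titration_series <- function(pKa = 6.4, hill_n = 1, shift_prot = 8.6,
                                  shift_neutral = 7.7, noise_sd = 0,
                                  pH = c(5.5, 6.0, 6.33, 6.67, 7.0, 7.33,
                                         7.67, 8.0),
                                  seed = 1L) {
  mu <- .hill_curve(pH, pKa, hill_n, shift_prot, shift_neutral)
  y <- if (noise_sd > 0) {
    with_local_seed(seed, mu + stats::rnorm(length(pH), 0, noise_sd))
  } else mu
  titration_series(pH, y)
}

#' Generate a synthetic turbidity series
#'
#' Absorbance follows a hinge: `A340 = max(0, slope * (c - threshold))`
#' plus optional Gaussian noise (clamped at 0 so absorbances stay
#' non-negative), emulating the onset shape of a phase-separation
#' turbidity assay.
#'
#' @param threshold planted x-intercept in uM.
#' @param slope absorbance per uM above threshold (default 0.004).
#' @param noise_sd Gaussian noise sd (default 0).
#' @param grid concentration grid in uM (default 50-500 by 50).
#' @param seed integer seed.
#' @return a [turbidity_series()].
#' @export
make_turbidity_series <- function(threshold = 125, slope = 0.004,
                                  noise_sd = 0,
                                  grid = seq(50, 500, by = 50), seed = 1L) {
  mu <- pmax(0, slope * (grid - threshold))
  y <- if (noise_sd > 0) {
    with_local_seed(seed, pmax(0, mu + stats::rnorm(length(grid), 0, noise_sd)))
  } else mu
  turbidity_series(grid, y)
}

#' Generate a feature table with planted principal components
#'
#' Constructs four correlated virial-feature columns from planted
#' orthogonal score directions with strictly decreasing variances, and
#' thresholds from the linear model
#' `threshold = a * PC1 + b * PC4 + c + noise`. The planted loadings obey
#' the same sign convention as [virial_pca()] (largest-magnitude loading
#' positive), so a noiseless table is recovered exactly — scores, loadings
#' and regression coefficients — by `virial_pca()` +
#' [mlr_on_components()].
#'
#' @param a,b,c linear-model coefficients (defaults 6.1, 413.4, 182.5).
#' @param noise_sd Gaussian noise sd on thresholds in uM (default 0).
#' @param n_rows number of (variant, pH) rows (default 30).
#' @param score_sd planted score standard deviations for PC1..PC4;
#'   strictly decreasing (default `c(20, 8, 3, 0.12)`, giving thresholds
#'   spanning roughly 50-350 uM with the default coefficients).
#' @param center planted feature-column means.
#' @param censor_rows integer row indices whose thresholds are reported as
#'   `NA` (non-phase-separating conditions) and imputed at `impute`.
#' @param impute imputation value for censored rows (default 400).
#' @param seed integer seed.
#' @return a [feature_table()] with attributes `planted_scores`,
#'   `planted_loadings` and `planted_thresholds`.
#' @export
make_feature_table <- function(a = 6.1, b = 413.4, c = 182.5, noise_sd = 0,
                               n_rows = 30, score_sd = c(20, 8, 3, 0.12),
                               center = c(-2, -4, -1, -3),
                               censor_rows = integer(0), impute = 400,
                               seed = 1L) {
  if (n_rows < 6) stopf("need at least 6 rows")
  if (any(diff(score_sd) >= 0)) stopf("score_sd must be strictly decreasing")
  gen <- with_local_seed(seed, {
    z <- cbind(1, matrix(stats::rnorm(n_rows * 4), ncol = 4))
    Q <- qr.Q(qr(z))[, 2:5, drop = FALSE]  # orthonormal, mean-zero columns
    L <- qr.Q(qr(matrix(stats::rnorm(16), 4, 4)))
    eps <- if (noise_sd > 0) stats::rnorm(n_rows, 0, noise_sd) else numeric(n_rows)
    list(Q = Q, L = L, eps = eps)
  })
  S <- sweep(gen$Q, 2, score_sd * sqrt(n_rows - 1), "*")
  L <- gen$L
  for (j in 1:4) {  # sign convention shared with virial_pca()
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) { L[, j] <- -L[, j]; S[, j] <- -S[, j] }
  }
  X <- S %*% t(L)
  X <- sweep(X, 2, center, "+")
  thr <- a * S[, 1] + b * S[, 4] + c + gen$eps
  thr_obs <- thr
  thr_obs[censor_rows] <- NA
  variants <- sprintf("V%02d", rep(seq_len(ceiling(n_rows / 2)), each = 2))[seq_len(n_rows)]
  pHs <- rep(c(7, 8), length.out = n_rows)
  ft <- feature_table(variants, pHs, X[, 1], X[, 2], X[, 3], X[, 4],
                      thr_obs, impute = impute)
  colnames(S) <- paste0("PC", 1:4)
  attr(ft, "planted_scores") <- S
  attr(ft, "planted_loadings") <- L
  attr(ft, "planted_thresholds") <- thr
  ft
}
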