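# FFT-accelerated integration of the Mayer f-function over rigid-body
# translations and sampled orientations, yielding second osmotic virial
# coefficients (A2) and cross second virial coefficients (A23), with
# Boltzmann averaging over protonation microstates.
#
# Convention used throughout: the raw volume integral is
#   B = -(1/2) * mean_over_orientations( sum_cells (exp(-U/kBT) - 1) h^3 )
# in Angstrom^3, for both A2 and A23 (cross-coefficient conventions differ
# in the literature; this package uses the same -1/2 prefactor for both).
# Mass units: A = N_A * B * 1e-24 / (M_A * M_B) in mol mL g^-2.

#' Sample a reproducible set of orientations
#'
#' Draws `n` rotation matrices quasi-uniformly over SO(3) (uniform random
#' quaternions, Shoemake construction) from a dedicated RNG stream, so the
#' set is reproducible for fixed `(n, seed)` and does not perturb the
#' caller's RNG. With `n = 1` the identity rotation is returned.
#'
#' @param n number of orientations (>= 1).
#' @param seed integer seed.
#' @return object of class `orientation_set`: list with `rotations` (list
#'   of 3x3 matrices), `scheme`, `seed`, `n`.
#' @export
sample_orientations <- function(n, seed = 1L) {
  if (n < 1) stopf("n must be >= 1")
  n <- as.integer(n)
  if (n == 1L) {
    rots <- list(diag(3))
  } else {
    rots <- with_local_seed(seed, {
      u <- matrix(stats::runif(3L * n), ncol = 3)
      lapply(seq_len(n), function(i) {
        u1 <- u[i, 1]; t2 <- 2 * pi * u[i, 2]; t3 <- 2 * pi * u[i, 3]
        q <- c(sqrt(1 - u1) * sin(t2), sqrt(1 - u1) * cos(t2),
               sqrt(u1) * sin(t3), sqrt(u1) * cos(t3))
        quat_to_mat(q)
      })
    })
  }
  structure(list(rotations = rots, scheme = "shoemake", seed = seed, n = n),
            class = "orientation_set")
}

# unit quaternion (x, y, z, w) -> 3x3 rotation matrix
quat_to_mat <- function(q) {
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

# ---------------------------------------------------------------------------
# Grid machinery. Atom coordinates are snapped to a cubic lattice of the
# requested spacing; the energy at every lattice displacement of body B
# relative to body A is then an exact cyclic cross-correlation, evaluated
# with FFTs. The box is sized so that the cyclic correlation equals the
# linear one within the interaction truncation radius r_cut (no
# wrap-around aliasing).

.default_r_cut <- function(p) p$r_cut %||% max(3 / max(p$kappa, 1e-12), 16)

# signed lattice displacement values for an axis of length n
.signed_axis <- function(n) {
  v <- 0:(n - 1)
  ifelse(v > n / 2, v - n, v)
}

# 3-D array of |displacement| in Angstrom over the cyclic grid
.dist_array <- function(N, h) {
  s1 <- .signed_axis(N[1]); s2 <- .signed_axis(N[2]); s3 <- .signed_axis(N[3])
  d2 <- outer(s1^2, s2^2, "+")
  d2 <- array(rep(d2, N[3]), dim = N) +
    array(rep(s3^2, each = N[1] * N[2]), dim = N)
  h * sqrt(d2)
}

# deposit weights w at integer lattice points k (n x 3) into an N-array
.deposit <- function(k, w, N) {
  arr <- array(0, dim = N)
  i <- (k[, 1] %% N[1]) + 1L
  j <- (k[, 2] %% N[2]) + 1L
  l <- (k[, 3] %% N[3]) + 1L
  for (a in seq_along(w)) arr[i[a], j[a], l[a]] <- arr[i[a], j[a], l[a]] + w[a]
  arr
}

# cyclic cross-correlation E(k) = sum_{i,j} wA_i wB_j K(b_j - a_i + k)
# given the FFTs of the deposited grids and of the kernel
.corr3 <- function(FA, FB, FK) {
  Re(stats::fft(FA * Conj(FB) * FK, inverse = TRUE)) / length(FA)
}

# Core scan over all lattice displacements for one orientation.
# xa, xb: coordinate matrices (xb already rotated); ra, rb: radii;
# charge_sets: list of list(qa=, qb=) per protonation microstate.
# Returns shared clash/nonpolar arrays and one electrostatic array per set.
.scan_core <- function(xa, ra, xb, rb, charge_sets, spacing, p,
                       r_cut = .default_r_cut(p)) {
  h <- spacing
  ka <- round(xa / h); kb <- round(xb / h)
  storage.mode(ka) <- "integer"; storage.mode(kb) <- "integer"
  span <- function(k) apply(k, 2, function(v) diff(range(v))) * h
  ext <- span(ka) + span(kb) + 2 * r_cut
  N <- vapply(ext, function(e) stats::nextn(as.integer(ceiling(e / h)) + 3L,
                                            c(2L, 3L, 5L)), integer(1))
  dist <- .dist_array(N, h)
  in_range <- dist > 0 & dist <= r_cut

  ua <- sort(unique(ra)); ub <- sort(unique(rb))
  FA_cnt <- lapply(ua, function(u) stats::fft(.deposit(
    ka[ra == u, , drop = FALSE], rep(1, sum(ra == u)), N)))
  FB_cnt <- lapply(ub, function(u) stats::fft(.deposit(
    kb[rb == u, , drop = FALSE], rep(1, sum(rb == u)), N)))

  clash_cnt <- array(0, dim = N)
  nonpolar <- array(0, dim = N)
  for (i in seq_along(ua)) for (j in seq_along(ub)) {
    sigma <- ua[i] + ub[j]
    kc <- array(as.numeric(dist < p$clash_factor * sigma), dim = N)
    clash_cnt <- clash_cnt + .corr3(FA_cnt[[i]], FB_cnt[[j]], stats::fft(kc))
    if (p$lj_well_depth != 0) {
      sr6 <- ifelse(in_range, (sigma / pmax(dist, 1e-12))^6, 0)
      klj <- p$lj_well_depth * (sr6^2 - 2 * sr6)
      nonpolar <- nonpolar + .corr3(FA_cnt[[i]], FB_cnt[[j]], stats::fft(klj))
    }
  }
  clash <- clash_cnt > 0.5

  ke <- ifelse(in_range, p$bjerrum * exp(-p$kappa * dist) / pmax(dist, 1e-12), 0)
  FK_e <- stats::fft(ke)
  elec <- lapply(charge_sets, function(cs) {
    if (all(cs$qa == 0) || all(cs$qb == 0)) return(array(0, dim = N))
    FAq <- stats::fft(.deposit(ka, cs$qa, N))
    FBq <- stats::fft(.deposit(kb, cs$qb, N))
    .corr3(FAq, FBq, FK_e)
  })

  list(N = N, spacing = h, r_cut = r_cut, ka = ka, kb = kb,
       clash = clash, nonpolar = nonpolar, elec = elec)
}

.field_from_core <- function(core, state_idx, rotation, rotation_id,
                             microstate_id = state_idx, charges = NULL) {
  total <- core$nonpolar + core$elec[[state_idx]]
  total[core$clash] <- Inf
  structure(list(
    rotation_id = rotation_id, rotation = rotation,
    microstate_id = microstate_id,
    grid_spacing = core$spacing, dims = core$N, r_cut = core$r_cut,
    a_snap = core$ka, b_snap = core$kb,
    clash = core$clash, nonpolar = core$nonpolar,
    electrostatic = core$elec[[state_idx]], total = total,
    charges = charges), class = "energy_field")
}

#' Scan the pair energy over all lattice translations
#'
#' Computes the total interaction energy of bodies `A` and `B` (B rotated
#' by `rotation`) at every displacement of a cubic lattice with the given
#' spacing, via FFT cross-correlation. Atom positions are snapped to the
#' lattice; the returned values are exactly the direct atom-pair sums over
#' the snapped coordinates, with pair interactions truncated beyond the
#' model's `r_cut`. Clashing displacements are marked `Inf`.
#'
#' @param A,B `rigid_structure` objects.
#' @param rotation 3x3 rotation matrix applied to B.
#' @param p an [energy_params()] object.
#' @param spacing lattice spacing in Angstrom (default 0.6).
#' @param charges_A,charges_B optional per-atom charge overrides.
#' @param rotation_id integer label stored on the field.
#' @return object of class `energy_field`: arrays `total`, `nonpolar`,
#'   `electrostatic`, logical `clash`, plus grid metadata (`dims`,
#'   `grid_spacing`, `r_cut`, snapped atom indices).
#' @export
translational_scan <- function(A, B, rotation = diag(3), p = energy_params(),
                               spacing = 0.6, charges_A = NULL,
                               charges_B = NULL, rotation_id = 1L) {
  if (spacing <= 0) stopf("spacing must be > 0")
  if (spacing > min(c(A$atoms$radius, B$atoms$radius)))
    warnf("grid spacing %.3g A exceeds the smallest atomic radius; the scan will be coarse",
          spacing)
  xb <- coords(B) %*% t(rotation)
  qa <- charges_A %||% A$atoms$charge
  qb <- charges_B %||% B$atoms$charge
  core <- .scan_core(coords(A), A$atoms$radius, xb, B$atoms$radius,
                     list(list(qa = qa, qb = qb)), spacing, p)
  .field_from_core(core, 1L, rotation, rotation_id,
                   charges = list(qa = qa, qb = qb))
}

#' @export
print.energy_field <- function(x, ...) {
  nf <- sum(!x$clash)
  cat(sprintf("<energy_field> %d x %d x %d grid (h = %g A), %d clash-free cells, min U = %.3f kBT\n",
              x$dims[1], x$dims[2], x$dims[3], x$grid_spacing, nf,
              suppressWarnings(min(x$total[is.finite(x$total)]))))
  invisible(x)
}

#' Mayer volume integral over one or more energy fields
#'
#' Integrates the Mayer f-function `f = exp(-U/kBT) - 1` over all lattice
#' displacements, averaged over orientations (one field per orientation),
#' returning `B = -(1/2) * mean_rot sum_cells f * h^3` in Angstrom^3.
#' Clashing cells contribute exactly `f = -1`; finite energies are capped
#' at `p$energy_cap` before exponentiation as a numerical guard.
#'
#' @param fields an `energy_field` or list of them (one per orientation).
#' @param p an [energy_params()] object (supplies the cap).
#' @return volume integral in Angstrom^3 (negative = net repulsion
#'   dominates the Mayer volume; positive = attraction).
#' @export
mayer_integral <- function(fields, p = energy_params()) {
  if (inherits(fields, "energy_field")) fields <- list(fields)
  if (!length(fields)) stopf("need at least one energy field")
  sums <- vapply(fields, function(fl) {
    u <- fl$total
    f <- ifelse(is.infinite(u), -1, expm1(-pmin(u, p$energy_cap)))
    sum(f) * fl$grid_spacing^3
  }, numeric(1))
  -0.5 * mean(sums)
}

#' Convert a Mayer volume integral to mass-based virial units
#'
#' `A = N_A * B * 1e-24 / (M_A * M_B)`, converting Angstrom^3 per molecule
#' pair to mol mL g^-2. For a self coefficient (A2) the two masses are
#' equal.
#'
#' @param B volume integral in Angstrom^3.
#' @param M_A,M_B molar masses in g/mol (`M_B` defaults to `M_A`).
#' @return virial coefficient in mol mL g^-2.
#' @export
to_mass_units <- function(B, M_A, M_B = M_A) {
  if (M_A <= 0 || M_B <= 0) stopf("molar masses must be > 0")
  .const$avogadro * B * 1e-24 / (M_A * M_B)
}

# label for one joint microstate, e.g. "35+/43d" -> protonated/deprotonated
.state_label <- function(site_states) {
  if (!length(site_states)) return("-")
  paste0(names(site_states),
         ifelse(site_states == "protonated", "+", "0"), collapse = "/")
}

.virial_result <- function(kind, per_state, weights, labels, raw_B, M_A, M_B,
                           meta) {
  value <- sum(weights * per_state)
  structure(list(
    kind = kind, value = value,
    per_state_values = stats::setNames(per_state, labels),
    weights = stats::setNames(weights, labels),
    raw_volume_integral = sum(weights * raw_B),
    calibration_offset = 0,
    M_A = M_A, M_B = M_B, meta = meta), class = "virial_result")
}

#' @export
print.virial_result <- function(x, ...) {
  cat(sprintf("<virial_result> %s = %.4e mol mL g^-2 (%d protonation state%s, offset %.3g)\n",
              x$kind, x$value + x$calibration_offset,
              length(x$per_state_values),
              if (length(x$per_state_values) == 1) "" else "s",
              x$calibration_offset))
  invisible(x)
}

# shared driver for compute_A2 / compute_A23
.compute_virial <- function(A, B, charge_sets, weights, labels, kind,
                            p, n_orientations, spacing, seed, r_cut) {
  rots <- sample_orientations(n_orientations, seed)
  r_cut <- r_cut %||% .default_r_cut(p)
  xa <- coords(A); xb0 <- coords(B)
  nstate <- length(charge_sets)
  acc <- matrix(0, nrow = n_orientations, ncol = nstate)
  for (r in seq_len(n_orientations)) {
    R <- rots$rotations[[r]]
    core <- .scan_core(xa, A$atoms$radius, xb0 %*% t(R), B$atoms$radius,
                       charge_sets, spacing, p, r_cut)
    h3 <- core$spacing^3
    for (m in seq_len(nstate)) {
      u <- core$nonpolar + core$elec[[m]]
      f <- expm1(-pmin(u, p$energy_cap))
      f[core$clash] <- -1
      acc[r, m] <- sum(f) * h3
    }
  }
  B_int <- -0.5 * colMeans(acc)
  per_state <- to_mass_units(B_int, A$molar_mass, B$molar_mass)
  conv <- data.frame(
    n_orientations = seq_len(n_orientations),
    value = to_mass_units(
      -0.5 * cumsum(acc %*% weights) / seq_len(n_orientations),
      A$molar_mass, B$molar_mass))
  res <- .virial_result(kind, per_state, weights, labels, B_int,
                        A$molar_mass, B$molar_mass,
                        meta = list(n_orientations = n_orientations,
                                    spacing = spacing, seed = seed,
                                    r_cut = r_cut %||% .default_r_cut(p),
                                    params = p))
  res$convergence <- conv
  res
}

#' Second osmotic virial coefficient of a rigid structure
#'
#' Computes A2 by integrating the Mayer function over lattice translations
#' (FFT scan) and sampled orientations, for every protonation microstate of
#' the structure's titratable sites, then Boltzmann-averages the
#' per-microstate values with Henderson-Hasselbalch product weights at the
#' given pH. Both interacting copies of the molecule carry the same
#' microstate charge set, matching the convention of averaging the
#' coefficient over the molecule's protonation combinations.
#'
#' @param s a `rigid_structure` with positive molar mass.
#' @param pH solution pH (default 7).
#' @param p an [energy_params()] object.
#' @param n_orientations number of sampled orientations (default 600).
#' @param spacing lattice spacing in Angstrom (default 0.6).
#' @param seed orientation seed, recorded in the result metadata.
#' @param r_cut optional interaction truncation radius override (Angstrom).
#' @return object of class `virial_result`: Boltzmann-averaged `value`
#'   (mol mL g^-2), `per_state_values`, `weights`, the raw volume integral
#'   (Angstrom^3), `calibration_offset` (0 until [calibrate()]), and a
#'   per-orientation convergence table.
#' @export
compute_A2 <- function(s, pH = 7, p = energy_params(), n_orientations = 600,
                       spacing = 0.6, seed = 1L, r_cut = NULL) {
  ms <- enumerate_protonation(s, pH)
  charge_sets <- lapply(ms, function(m) list(qa = m$charges, qb = m$charges))
  weights <- vapply(ms, `[[`, numeric(1), "weight")
  labels <- vapply(ms, function(m) .state_label(m$site_states), character(1))
  .compute_virial(s, s, charge_sets, weights, labels, "A2",
                  p, n_orientations, spacing, seed, r_cut)
}

#' Cross second virial coefficient of two rigid structures
#'
#' As [compute_A2()] but for two distinct bodies, normalizing by
#' `M_A * M_B`. Protonation enumeration spans the titratable sites of both
#' bodies jointly (the joint weight is the product of the two bodies'
#' microstate weights).
#'
#' @param A,B `rigid_structure` objects.
#' @inheritParams compute_A2
#' @return a `virial_result` of kind `"A23"`.
#' @export
compute_A23 <- function(A, B, pH = 7, p = energy_params(),
                        n_orientations = 600, spacing = 0.6, seed = 1L,
                        r_cut = NULL) {
  msA <- enumerate_protonation(A, pH)
  msB <- enumerate_protonation(B, pH)
  charge_sets <- list(); weights <- c(); labels <- c()
  for (a in msA) for (b in msB) {
    charge_sets[[length(charge_sets) + 1L]] <-
      list(qa = a$charges, qb = b$charges)
    weights <- c(weights, a$weight * b$weight)
    labels <- c(labels, paste0("A:", .state_label(a$site_states),
                               "|B:", .state_label(b$site_states)))
  }
  .compute_virial(A, B, charge_sets, weights, labels, "A23",
                  p, n_orientations, spacing, seed, r_cut)
}

#' Calibrate calculated values to an experimental anchor
#'
#' Adds a single constant to all calculated values so that the value at the
#' anchor condition equals the supplied experimental value exactly; all
#' pairwise differences between conditions are preserved. This absorbs a
#' putatively constant contribution that the calculation omits (e.g.
#' flexible terminal residues excluded from the rigid model).
#'
#' @param values named numeric vector of calculated values by condition.
#' @param anchor_condition name of the anchoring condition.
#' @param anchor_value experimental value at the anchor.
#' @return list with `values` (shifted, same names) and `offset`.
#' @export
calibrate <- function(values, anchor_condition, anchor_value) {
  if (!anchor_condition %in% names(values))
    stopf("anchor condition '%s' not present", anchor_condition)
  offset <- anchor_value - values[[anchor_condition]]
  list(values = values + offset, offset = offset)
}
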