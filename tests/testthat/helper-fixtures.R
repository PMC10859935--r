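# Fixtures and independent oracles shared across tests.

# minimal structure from explicit fields
toy_structure <- function(x, y, z, charge, radius, residue_id = NULL,
                          residue_name = "GLY", molar_mass = NULL) {
  n <- length(x)
  rigid_structure(data.frame(
    atom_name = "X", residue_name = residue_name,
    residue_id = residue_id %||% seq_len(n), chain_id = "A",
    x = x, y = y, z = z, charge = charge, radius = radius),
    molar_mass = molar_mass)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force oracle for the translational scan: for every cell
# of the field's cyclic grid, sum the three-term pair energy over all atom
# pairs on the snapped lattice, truncating beyond r_cut, with min-image
# wrapping. Kept free of the package's FFT machinery.
direct_field <- function(A, B, rotation, p, fl, charges_A = NULL,
                         charges_B = NULL) {
  h <- fl$grid_spacing
  N <- fl$dims
  r_cut <- fl$r_cut
  ka <- round(as.matrix(A$atoms[, c("x", "y", "z")]) / h)
  xb <- as.matrix(B$atoms[, c("x", "y", "z")]) %*% t(rotation)
  kb <- round(xb / h)
  qa <- charges_A %||% A$atoms$charge
  qb <- charges_B %||% B$atoms$charge
  lB <- p$bjerrum; kap <- p$kappa
  sax <- function(n) { v <- 0:(n - 1); ifelse(v > n / 2, v - n, v) }
  wrap <- function(d, n) ((d + floor(n / 2)) %% n) - floor(n / 2)
  s1 <- sax(N[1]); s2 <- sax(N[2]); s3 <- sax(N[3])
  finite_sum <- array(0, N)
  clash <- array(FALSE, N)
  for (i in seq_len(nrow(ka))) for (j in seq_len(nrow(kb))) {
    del <- kb[j, ] - ka[i, ]
    dx <- wrap(del[1] + s1, N[1])
    dy <- wrap(del[2] + s2, N[2])
    dz <- wrap(del[3] + s3, N[3])
    d2 <- outer(dx^2, dy^2, "+")
    d <- h * sqrt(array(rep(d2, N[3]), N) +
                  array(rep(dz^2, each = N[1] * N[2]), N))
    sg <- A$atoms$radius[i] + B$atoms$radius[j]
    clash <- clash | (d < p$clash_factor * sg)
    ok <- d > 0 & d <= r_cut
    sr6 <- ifelse(ok, (sg / pmax(d, 1e-12))^6, 0)
    e <- p$lj_well_depth * (sr6^2 - 2 * sr6) +
      ifelse(ok, qa[i] * qb[j] * lB * exp(-kap * d) / pmax(d, 1e-12), 0)
    finite_sum <- finite_sum + e
  }
  total <- finite_sum
  total[clash] <- Inf
  list(total = total, clash = clash)
}

# a hand-built pose table over a single-orientation identity frame, so
# ligand RMSD between poses equals the Euclidean displacement distance
synthetic_pose_table <- function(displacements, energies, B, spacing = 1) {
  n <- nrow(displacements)
  poses <- data.frame(
    pose_id = seq_len(n), rotation_id = 1L, microstate_id = 1L,
    dx = displacements[, 1], dy = displacements[, 2],
    dz = displacements[, 3],
    nonpolar = 0, electrostatic = energies, total = energies)
  ord <- order(poses$total)
  poses <- poses[ord, , drop = FALSE]
  poses$pose_id <- seq_len(n)
  rownames(poses) <- NULL
  attr(poses, "fields_meta") <- list(`1` = list(
    rotation = diag(3),
    a_snap = matrix(0L, 1, 3),
    b_snap = round(as.matrix(B$atoms[, c("x", "y", "z")]) / spacing),
    spacing = spacing, r_cut = 16, microstate_id = 1L,
    charges = list(qa = 0, qb = B$atoms$charge)))
  class(poses) <- c("pose_table", "data.frame")
  poses
}
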