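# Virial engine: orientation sampling, FFT scan vs direct summation,
# Mayer integral oracles, unit conversion, A2/A23, calibration.

test_that("orientation sets are deterministic, orthonormal and quasi-uniform", {
  o1 <- sample_orientations(1)
  expect_identical(o1$rotations[[1]], diag(3))
  s1 <- sample_orientations(50, seed = 9)
  s2 <- sample_orientations(50, seed = 9)
  expect_identical(s1$rotations, s2$rotations)
  for (R in s1$rotations[1:10]) {
    expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
  # mean image of a fixed unit vector over many rotations is near zero
  v <- c(1, 0, 0)
  imgs <- vapply(sample_orientations(1000, seed = 4)$rotations,
                 function(R) R %*% v, numeric(3))
  expect_lt(sqrt(sum(rowMeans(imgs)^2)), 0.1)
  expect_error(sample_orientations(0), ">= 1")
})

test_that("FFT translational scan equals direct pair summation everywhere", {
  set.seed(5)
  p <- energy_params(r_cut = 10)
  A <- toy_structure(x = runif(3, -2, 2), y = runif(3, -2, 2),
                     z = runif(3, -2, 2), charge = c(0.5, -0.3, 0.2),
                     radius = c(1.5, 1.2, 2.0))
  B <- toy_structure(x = runif(2, -2, 2), y = runif(2, -2, 2),
                     z = runif(2, -2, 2), charge = c(-0.4, 0.6),
                     radius = c(1.8, 1.1))
  for (rot in list(diag(3), sample_orientations(3, 8)$rotations[[2]])) {
    fl <- translational_scan(A, B, rot, p, spacing = 0.8)
    ref <- direct_field(A, B, rot, p, fl)
    expect_identical(fl$clash, ref$clash)
    fin <- !ref$clash
    expect_lt(max(abs(fl$total[fin] - ref$total[fin])), 1e-6)
  }
})

test_that("scan marks hard-sphere clash region and is zero elsewhere without forces", {
  p <- energy_params(clash_factor = 1, lj_well_depth = 0, r_cut = 9)
  A <- toy_structure(0, 0, 0, 0, radius = 3)
  fl <- translational_scan(A, A, diag(3), p, spacing = 0.5)
  # infinite exactly where |R| < 2r on the lattice
  s <- fl$grid_spacing
  idx <- which(fl$clash, arr.ind = TRUE)
  sax <- function(n) { v <- 0:(n - 1); ifelse(v > n / 2, v - n, v) }
  d <- s * sqrt(sax(fl$dims[1])[idx[, 1]]^2 + sax(fl$dims[2])[idx[, 2]]^2 +
                sax(fl$dims[3])[idx[, 3]]^2)
  expect_true(all(d < 6))
  expect_equal(sum(fl$total[!fl$clash]), 0)
  expect_warning(translational_scan(A, A, diag(3), p, spacing = 4),
                 "coarse")
})

test_that("Mayer integral reproduces the hard-sphere closed form", {
  # steric-only: B = (2 pi / 3) sigma^3, sigma the hard contact diameter
  p <- energy_params(clash_factor = 1, lj_well_depth = 0, r_cut = 12)
  A <- toy_structure(0, 0, 0, 0, radius = 5)
  fl <- translational_scan(A, A, diag(3), p, spacing = 0.5)  # sigma/20
  B <- mayer_integral(fl, p)
  exact <- 2 * pi / 3 * 10^3
  expect_lt(abs(B - exact) / exact, 0.03)
  # U = 0 everywhere -> zero integral
  fl0 <- fl; fl0$total <- array(0, fl$dims); fl0$clash <- array(FALSE, fl$dims)
  expect_equal(mayer_integral(fl0, p), 0)
  # adding an attractive well outside the core lowers B strictly
  fl2 <- fl
  shell <- !fl$clash & is.finite(fl$total)
  fl2$total[shell] <- -0.2
  expect_lt(mayer_integral(fl2, p), B)
})

test_that("mass-unit conversion follows N_A * B * 1e-24 / (M_A M_B)", {
  expect_equal(to_mass_units(1, 1), 6.02214076e-1, tolerance = 1e-9)
  expect_equal(sign(to_mass_units(-3, 100)), -1)
  # hard spheres sigma = 40 A at M = 11 kg/mol, by hand
  hand <- (2 * pi / 3) * 64000 * 6.02214076e23 * 1e-24 / 11000^2
  expect_equal(to_mass_units(2 * pi / 3 * 40^3, 11000), hand,
               tolerance = 1e-12)
  expect_error(to_mass_units(1, -5), "> 0")
})

test_that("A2 responds to pH through a titratable charge patch", {
  # a +1 patch that titrates on at low pH, facing a fixed -1 patch:
  # more attraction (lower A2) when protonated
  toy <- make_toy_body("two-patch", titratable_patch = TRUE, seed = 3)
  p <- energy_params(r_cut = 12)
  r5 <- compute_A2(toy, pH = 5, p, n_orientations = 8, spacing = 1.5, seed = 2)
  r9 <- compute_A2(toy, pH = 9, p, n_orientations = 8, spacing = 1.5, seed = 2)
  expect_lt(r5$value, r9$value)
  # averaged value is a convex combination of the per-state values
  expect_gte(r5$value, min(r5$per_state_values))
  expect_lte(r5$value, max(r5$per_state_values))
  expect_equal(sum(r5$weights), 1, tolerance = 1e-12)

  # with charges stripped, A2 is pH-independent (steric + LJ only)
  neut <- toy; neut$atoms$charge <- 0; neut$titratable_sites <- neut$titratable_sites[0, ]
  n5 <- compute_A2(neut, pH = 5, p, n_orientations = 4, spacing = 1.5, seed = 2)
  n9 <- compute_A2(neut, pH = 9, p, n_orientations = 4, spacing = 1.5, seed = 2)
  expect_equal(n5$value, n9$value, tolerance = 1e-12)
})

test_that("A23 against an identical copy matches A2 for non-titratable bodies", {
  toy <- make_toy_body("two-patch", seed = 5)  # fixed +/- patches, no His
  p <- energy_params(r_cut = 12)
  a2 <- compute_A2(toy, 7, p, n_orientations = 5, spacing = 1.5, seed = 4)
  a23 <- compute_A23(toy, toy, 7, p, n_orientations = 5, spacing = 1.5, seed = 4)
  expect_equal(a23$value, a2$value, tolerance = 1e-9)
})

test_that("cross-coefficient becomes more negative when the basic patch is on", {
  body <- make_toy_body("two-patch", titratable_patch = TRUE, seed = 6)
  pep <- make_toy_body("linear-peptide", n_atoms = 5, net_charge = -3, seed = 7)
  p <- energy_params(r_cut = 12)
  lo <- compute_A23(body, pep, pH = 5, p, n_orientations = 8, spacing = 1.5, seed = 3)
  hi <- compute_A23(body, pep, pH = 9, p, n_orientations = 8, spacing = 1.5, seed = 3)
  expect_lt(lo$value, hi$value)
})

test_that("A2 is invariant to a rigid transform of the input structure", {
  s <- make_toy_body("sphere-shell", n_atoms = 32, net_charge = -4, seed = 8)
  p <- energy_params(r_cut = 10)
  base <- compute_A2(s, 7, p, n_orientations = 12, spacing = 1.2, seed = 5)
  R <- sample_orientations(2, 31)$rotations[[2]]
  s2 <- s
  s2$atoms[, c("x", "y", "z")] <-
    coords(s) %*% t(R) + matrix(c(8.3, -5.1, 2.9), nrow(coords(s)), 3,
                                byrow = TRUE)
  moved <- compute_A2(s2, 7, p, n_orientations = 12, spacing = 1.2, seed = 5)
  expect_lt(abs(moved$value - base$value) / abs(base$value), 0.05)
})

test_that("A2 is converged in orientation count for a near-isotropic body", {
  s <- make_toy_body("sphere-shell", n_atoms = 32, net_charge = -4, seed = 8)
  p <- energy_params(r_cut = 10)
  a <- compute_A2(s, 7, p, n_orientations = 8, spacing = 1.2, seed = 6)
  b <- compute_A2(s, 7, p, n_orientations = 16, spacing = 1.2, seed = 6)
  expect_lt(abs(b$value - a$value) / abs(b$value), 0.10)
  # convergence trace is exposed and ends at the reported value
  expect_equal(tail(b$convergence$value, 1), sum(b$weights * b$per_state_values),
               tolerance = 1e-12)
})

test_that("calibration shifts all values by one constant anchored to experiment", {
  v <- c(a = 1, b = 3, c = -2)
  cal <- calibrate(v, "a", 0)
  expect_equal(unname(cal$values), c(0, 2, -3))
  expect_equal(cal$offset, -1)
  # anchor already matching -> zero offset
  expect_equal(calibrate(v, "b", 3)$offset, 0)
  expect_error(calibrate(v, "zz", 1), "not present")
  # property: offset = anchor - raw and pairwise differences preserved
  set.seed(12)
  for (i in 1:10) {
    v <- setNames(rnorm(5), letters[1:5])
    anch <- sample(letters[1:5], 1); target <- rnorm(1)
    cal <- calibrate(v, anch, target)
    expect_equal(cal$offset, target - v[[anch]])
    expect_equal(diff(cal$values), diff(v), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(cal$values[[anch]], target)
  }
})
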