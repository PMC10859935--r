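# Pose mining, residue decomposition, ligand RMSD and clustering.

make_fields <- function(n_rot = 3, seed = 7) {
  p <- energy_params(r_cut = 10)
  body <- make_toy_body("two-patch", seed = 5)
  pep <- make_toy_body("linear-peptide", n_atoms = 5, net_charge = -2, seed = 6)
  rots <- sample_orientations(n_rot, seed)
  fields <- lapply(seq_len(n_rot), function(r) {
    translational_scan(body, pep, rots$rotations[[r]], p, spacing = 1.5,
                       rotation_id = r)
  })
  list(fields = fields, body = body, pep = pep, p = p)
}

test_that("top-k extraction matches a full sort of the flattened fields", {
  fx <- make_fields(2)
  poses <- top_k_poses(fx$fields, 150)
  expect_equal(nrow(poses), 150L)
  expect_true(all(diff(poses$total) >= 0))
  # brute force: flatten every finite cell and sort
  all_fin <- sort(unlist(lapply(fx$fields, function(f) f$total[is.finite(f$total)])))
  expect_equal(poses$total, all_fin[1:150], tolerance = 1e-12)
  # requesting more than available returns everything with a warning
  expect_warning(p_all <- top_k_poses(fx$fields, 10 * length(all_fin)),
                 "clash-free")
  expect_equal(nrow(p_all), length(all_fin))
  # idempotent under duplication of the input fields
  dup <- top_k_poses(c(fx$fields, fx$fields), 150)
  expect_equal(dup$total, poses$total, tolerance = 1e-12)
})

test_that("per-residue decomposition conserves pose totals", {
  fx <- make_fields(2)
  poses <- top_k_poses(fx$fields, 60)
  dec <- decompose_by_residue(fx$body, fx$pep, poses, fx$p)
  expect_equal(sum(dec$mean_contribution), attr(dec, "mean_total"),
               tolerance = 1e-9)
  # per-partner attribution: each side's residues sum to the mean total
  dec2 <- decompose_by_residue(fx$body, fx$pep, poses, fx$p,
                               attribution = "partner")
  expect_equal(sum(dec2$mean_contribution[dec2$partner == "A"]),
               attr(dec2, "mean_total"), tolerance = 1e-9)
  expect_equal(sum(dec2$mean_contribution[dec2$partner == "B"]),
               attr(dec2, "mean_total"), tolerance = 1e-9)
})

test_that("a residue with no interactions in range contributes nothing", {
  # two-residue body: residue 2 is neutral, LJ-free contact impossible
  A <- rigid_structure(data.frame(
    atom_name = "X", residue_name = "GLY", residue_id = c(1L, 2L),
    chain_id = "A", x = c(0, 40), y = 0, z = 0,
    charge = c(0.5, 0), radius = 1.5))
  B <- toy_structure(0, 0, 0, -0.5, 1.5)
  p <- energy_params(r_cut = 12)
  fl <- translational_scan(A, B, diag(3), p, spacing = 1.0)
  poses <- top_k_poses(fl, 20)
  dec <- decompose_by_residue(A, B, poses, p)
  c2 <- dec$mean_contribution[dec$partner == "A" & dec$residue_id == 2]
  expect_lt(abs(c2), 1e-9)
})

test_that("ligand RMSD matches analytic displacements and rotations", {
  B <- make_toy_body("linear-peptide", n_atoms = 4, seed = 9)
  id <- list(rotation = diag(3), displacement = c(0, 0, 0))
  expect_equal(ligand_rmsd(id, id, B), 0)
  tr <- list(rotation = diag(3), displacement = c(3, 0, 0))
  expect_equal(ligand_rmsd(id, tr, B), 3.0, tolerance = 1e-12)
  # 4-atom square rotated 90 degrees about its center: every atom moves
  # r * sqrt(2), so the RMSD is exactly r * sqrt(2)
  r <- 2.5
  sq <- toy_structure(x = c(r, 0, -r, 0), y = c(0, r, 0, -r), z = c(0, 0, 0, 0),
                      charge = rep(0, 4), radius = rep(1.5, 4))
  rot90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  expect_equal(ligand_rmsd(id, list(rotation = rot90, displacement = c(0, 0, 0)),
                           sq), r * sqrt(2), tolerance = 1e-12)
})

test_that("greedy single-linkage clustering keeps only well-populated clusters", {
  B <- toy_structure(0, 0, 0, 0, 1.5)  # single atom: RMSD = displacement
  set.seed(13)
  tight <- cbind(runif(12, -1, 1), runif(12, -1, 1), runif(12, -1, 1))
  stray <- cbind(50 + runif(3), runif(3), runif(3))
  disp <- rbind(tight, stray)
  poses <- synthetic_pose_table(disp, energies = seq(-5, by = 0.1,
                                                     length.out = 15), B)
  cl <- cluster_poses(poses, B, cutoff = 9, min_size = 10)
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$size, 12L)
  # representative is the lowest-energy member
  expect_equal(cl$clusters$representative, 1L)
  # the pre-filter assignment is a partition: everyone labelled exactly once
  expect_false(anyNA(cl$membership_all))
  expect_equal(sum(table(cl$membership_all)), 15L)

  # infinite cutoff lumps everything together
  cl_all <- cluster_poses(poses, B, cutoff = Inf, min_size = 1)
  expect_equal(nrow(cl_all$clusters), 1L)
  expect_equal(cl_all$clusters$size, 15L)
})
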