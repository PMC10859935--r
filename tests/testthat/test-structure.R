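# Rigid-structure handling: PQR IO, slicing, mutation, protonation.

make_pqr_lines <- function(first = 14, last = 97) {
  ids <- first:last
  sprintf("ATOM %d CA GLY A %d %.3f %.3f %.3f %.4f %.4f",
          seq_along(ids), ids, 3.8 * seq_along(ids), 0, 0, 0.0, 1.7)
}

test_that("PQR parsing reads fields, groups residues and round-trips", {
  ln <- "ATOM 1 CA GLY A 1 1.000 2.000 3.000 0.5000 1.5000"
  s <- read_pqr(ln)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(sum(s$atoms$charge), 0.5)
  expect_equal(s$atoms$radius, 1.5)
  expect_equal(s$atoms$chain_id, "A")

  # a residue window emulating a domain prepared as residues 14..97
  s2 <- read_pqr(make_pqr_lines(14, 97))
  expect_equal(n_residues(s2), 84L)

  # write -> read reproduces all fields (modulo float formatting)
  tf <- tempfile(fileext = ".pqr")
  write_pqr(s2, tf)
  s3 <- read_pqr(tf)
  expect_equal(s3$atoms$residue_id, s2$atoms$residue_id)
  expect_equal(s3$atoms$x, s2$atoms$x, tolerance = 1e-6)
  expect_equal(s3$atoms$charge, s2$atoms$charge, tolerance = 1e-6)

  # chainless 10-field dialect
  s4 <- read_pqr("ATOM 1 CA GLY 7 0 0 0 -1.0 2.0")
  expect_equal(s4$atoms$residue_id, 7L)
  expect_equal(s4$atoms$chain_id, "")

  expect_error(read_pqr("ATOM 1 CA GLY A 1 1 2 zz 0.5 1.5"), "line 1")
  expect_error(read_pqr("REMARK nothing"), "no ATOM")
})

test_that("conformation slicing is inclusive, idempotent and validated", {
  s <- read_pqr(make_pqr_lines(1, 10))
  sl <- slice_conformation(s, 3, 7)
  expect_equal(n_residues(sl), 5L)
  expect_identical(slice_conformation(sl, 3, 7)$atoms, sl$atoms)
  # full-range slice is the identity on atoms
  expect_identical(slice_conformation(s, 1, 10)$atoms, s$atoms)
  expect_error(slice_conformation(s, 11, 20), "does not intersect")

  # closed-minus-open difference is exactly the leading tail
  closed <- slice_conformation(read_pqr(make_pqr_lines(14, 97)), 14, 97, "closed")
  open <- slice_conformation(closed, 21, 97, "open")
  tail_ids <- setdiff(unique(closed$atoms$residue_id),
                      unique(open$atoms$residue_id))
  expect_equal(tail_ids, 14:20)
})

test_that("approximate mutation rewires residue identity, charge and titration", {
  # His residue with imidazole-like atoms plus backbone
  atoms <- data.frame(
    atom_name = c("N", "CA", "C", "O", "CB", "CG", "ND1", "CE1", "NE2", "CD2"),
    residue_name = "HIS", residue_id = 35L, chain_id = "A",
    x = c(0, 1.5, 2.5, 3.5, 1.5, 2.0, 2.5, 3.5, 3.8, 2.9),
    y = c(0, 0, 1, 1, -1.4, -2.6, -3.6, -4.4, -3.9, -2.8),
    z = 0, charge = 0, radius = 1.6)
  flank <- data.frame(
    atom_name = "CA", residue_name = "GLY",
    residue_id = c(34L, 36L), chain_id = "A",
    x = c(-3, 6), y = 0, z = 0, charge = c(0.1, -0.1), radius = 1.7)
  s <- rigid_structure(rbind(flank[1, ], atoms, flank[2, ]))
  expect_equal(s$titratable_sites$residue_id, 35L)

  m <- apply_mutation(s, "H35S")
  expect_true(all(m$atoms$residue_name[m$atoms$residue_id == 35] == "SER"))
  expect_equal(nrow(m$titratable_sites), 0L)
  # atoms outside the mutated residue untouched
  expect_identical(m$atoms[m$atoms$residue_id != 35, ],
                   s$atoms[s$atoms$residue_id != 35, ],
                   ignore_attr = TRUE)

  # Arg target: fixed +1 net residue charge, independent of pH machinery
  r <- apply_mutation(s, "H35R")
  expect_equal(sum(r$atoms$charge[r$atoms$residue_id == 35]), 1)
  expect_equal(nrow(r$titratable_sites), 0L)

  expect_error(apply_mutation(s, "H999S"), "not present")
  expect_error(apply_mutation(s, "K35S"), "mismatch")
  expect_error(apply_mutation(s, "H35X"), "unknown target")
})

test_that("protonation microstates enumerate 2^n combinations with product weights", {
  mk_his <- function(ids) {
    n <- length(ids)
    toy_structure(x = 5 * seq_len(n), y = 0 * ids, z = 0 * ids,
                  charge = 0 * ids, radius = rep(1.6, n),
                  residue_id = ids, residue_name = "HIS")
  }
  # three histidines -> eight microstates
  ms <- enumerate_protonation(mk_his(c(35, 43, 75)), pH = 7)
  expect_length(ms, 8L)
  expect_equal(sum(vapply(ms, `[[`, numeric(1), "weight")), 1, tolerance = 1e-12)

  # no titratable sites -> one microstate of weight 1
  s0 <- toy_structure(0, 0, 0, 0.3, 1.5)
  ms0 <- enumerate_protonation(s0, 7)
  expect_length(ms0, 1L)
  expect_equal(ms0[[1]]$weight, 1)

  # at pH = pKa each combination is equally likely: all-protonated = 1/8
  msq <- enumerate_protonation(mk_his(c(1, 2, 3)), pH = 6.3)
  allprot <- Filter(function(m) all(m$site_states == "protonated"), msq)
  expect_equal(allprot[[1]]$weight, 0.125, tolerance = 1e-12)

  # charge-sum contract: each site's atoms net +1 when protonated, 0 when not
  s1 <- mk_his(42)
  for (m in enumerate_protonation(s1, 6.8)) {
    want <- if (m$site_states[["42"]] == "protonated") 1 else 0
    expect_equal(sum(m$charges), want, tolerance = 1e-6)
  }
})

test_that("microstate weights sum to one across random pH/pKa/site counts", {
  set.seed(71)
  for (rep in 1:20) {
    nsites <- sample(0:4, 1)
    ids <- seq_len(max(nsites, 1))
    s <- toy_structure(x = 5 * ids, y = 0 * ids, z = 0 * ids,
                       charge = 0 * ids, radius = rep(1.5, length(ids)),
                       residue_id = ids,
                       residue_name = ifelse(ids <= nsites, "HIS", "GLY"))
    s$titratable_sites$pKa <- runif(nrow(s$titratable_sites), 4, 9)
    ms <- enumerate_protonation(s, pH = runif(1, 3, 11))
    expect_length(ms, 2^nsites)
    expect_equal(sum(vapply(ms, `[[`, numeric(1), "weight")), 1,
                 tolerance = 1e-12)
  }
})

test_that("molar mass comes from residue composition and accepts overrides", {
  s <- read_pqr(make_pqr_lines(1, 10))
  expect_equal(s$molar_mass, 10 * 57.0519 + 18.0153, tolerance = 1e-6)
  s2 <- read_pqr(make_pqr_lines(1, 10), molar_mass = 12345)
  expect_equal(s2$molar_mass, 12345)
})
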