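# Mining of lowest-energy binary configurations from energy fields,
# per-residue decomposition of their interaction energies, and greedy
# single-linkage clustering by ligand RMSD.

#' Extract the lowest-energy poses from energy fields
#'
#' Flattens one or more [translational_scan()] fields (typically one per
#' orientation) and returns the `k` clash-free lattice configurations with
#' the smallest total energies, in ascending order. Ties are broken by
#' `(rotation_id, dz, dy, dx)` lexicographically so the extraction is
#' deterministic.
#'
#' @param fields an `energy_field` or list of them.
#' @param k number of poses to keep (default 1000). If fewer clash-free
#'   cells exist, all are returned with a warning.
#' @return data frame of class `pose_table`: columns `pose_id`,
#'   `rotation_id`, `microstate_id`, `dx`, `dy`, `dz` (Angstrom, lattice
#'   displacement of B relative to A's frame), `nonpolar`,
#'   `electrostatic`, `total` (kBT). Field metadata needed to reconstruct
#'   coordinates (rotations, snapped indices, spacing, charges, `r_cut`)
#'   is attached as attribute `"fields_meta"`.
#' @export
top_k_poses <- function(fields, k = 1000) {
  if (inherits(fields, "energy_field")) fields <- list(fields)
  if (k < 1) stopf("k must be >= 1")
  rows <- list()
  meta <- list()
  for (fl in fields) {
    rid <- fl$rotation_id
    meta[[as.character(rid)]] <- list(
      rotation = fl$rotation, a_snap = fl$a_snap, b_snap = fl$b_snap,
      spacing = fl$grid_spacing, r_cut = fl$r_cut, charges = fl$charges,
      microstate_id = fl$microstate_id %||% 1L)
    fin <- which(is.finite(fl$total))
    if (!length(fin)) next
    tot <- fl$total[fin]
    # keep only a generous per-field shortlist before the global sort
    keep <- fin[order(tot)[seq_len(min(length(fin), k))]]
    ind <- arrayInd(keep, fl$dims)
    s1 <- .signed_axis(fl$dims[1]); s2 <- .signed_axis(fl$dims[2])
    s3 <- .signed_axis(fl$dims[3])
    h <- fl$grid_spacing
    rows[[length(rows) + 1L]] <- data.frame(
      rotation_id = rid, microstate_id = fl$microstate_id %||% 1L,
      dx = h * s1[ind[, 1]], dy = h * s2[ind[, 2]], dz = h * s3[ind[, 3]],
      nonpolar = fl$nonpolar[keep], electrostatic = fl$electrostatic[keep],
      total = fl$total[keep])
  }
  if (!length(rows)) stopf("no clash-free cells in any field")
  poses <- do.call(rbind, rows)
  # re-supplying the same field leaves the extraction unchanged
  poses <- poses[!duplicated(poses[, c("rotation_id", "microstate_id",
                                       "dx", "dy", "dz")]), , drop = FALSE]
  ord <- order(poses$total, poses$rotation_id, poses$dz, poses$dy, poses$dx)
  poses <- poses[ord, , drop = FALSE]
  if (nrow(poses) < k)
    warnf("only %d clash-free configurations available (requested %d)",
          nrow(poses), k)
  poses <- utils::head(poses, k)
  poses <- cbind(pose_id = seq_len(nrow(poses)), poses)
  rownames(poses) <- NULL
  attr(poses, "fields_meta") <- meta
  class(poses) <- c("pose_table", "data.frame")
  poses
}

# snapped lattice coordinates (Angstrom) of A and of B placed at pose i
.pose_coords <- function(poses, i) {
  m <- attr(poses, "fields_meta")[[as.character(poses$rotation_id[i])]]
  h <- m$spacing
  list(xa = m$a_snap * h,
       xb = sweep(m$b_snap * h, 2,
                  c(poses$dx[i], poses$dy[i], poses$dz[i]), "+"),
       meta = m)
}

#' Per-residue decomposition of pose interaction energies
#'
#' Splits the total interaction energy of each pose into residue
#' contributions and averages them over all poses. With the default
#' `"half"` attribution each atom-pair energy is credited half to the
#' residue on each side, so the grand total over both partners' residues
#' equals the mean pose energy exactly. With `"partner"` attribution each
#' pair's full energy is credited to the residue on each side separately
#' (each partner's residue sums then equal the mean total on their own).
#'
#' The decomposition replays the scan's pair rules (snapped lattice
#' coordinates, truncation at `r_cut`), so it conserves the pose totals to
#' numerical round-off.
#'
#' @param A,B the `rigid_structure` objects that produced the fields.
#' @param poses a `pose_table` from [top_k_poses()].
#' @param p the [energy_params()] used for the scan.
#' @param attribution `"half"` (default) or `"partner"`.
#' @return data frame with columns `partner` (`"A"`/`"B"`), `chain_id`,
#'   `residue_id`, `residue_name`, `mean_contribution` (kBT, averaged over
#'   poses). Attribute `"mean_total"` carries the mean pose energy.
#' @export
decompose_by_residue <- function(A, B, poses, p = energy_params(),
                                 attribution = c("half", "partner")) {
  attribution <- match.arg(attribution)
  if (!nrow(poses)) stopf("empty pose table")
  resA <- paste(A$atoms$chain_id, A$atoms$residue_id)
  resB <- paste(B$atoms$chain_id, B$atoms$residue_id)
  uA <- unique(resA); uB <- unique(resB)
  iA <- match(resA, uA); iB <- match(resB, uB)
  accA <- numeric(length(uA)); accB <- numeric(length(uB))
  w <- if (attribution == "half") 0.5 else 1.0
  for (i in seq_len(nrow(poses))) {
    pc <- .pose_coords(poses, i)
    qa <- pc$meta$charges$qa; qb <- pc$meta$charges$qb
    d2 <- outer(rowSums(pc$xa^2), rowSums(pc$xb^2), "+") -
      2 * pc$xa %*% t(pc$xb)
    d <- sqrt(pmax(d2, 0))
    tm <- pair_terms(as.vector(d), as.vector(outer(qa, qb)),
                     as.vector(outer(A$atoms$radius, B$atoms$radius, "+")),
                     p, r_cut = pc$meta$r_cut)
    e <- matrix(tm$nonpolar + tm$electrostatic,
                nrow = nrow(pc$xa))
    # rowsum groups by residue index; indices are 1..n_residues so the
    # sorted group order matches the first-appearance residue order
    accA <- accA + w * as.vector(rowsum(rowSums(e), iA))
    accB <- accB + w * as.vector(rowsum(colSums(e), iB))
  }
  n <- nrow(poses)
  firstA <- !duplicated(resA); firstB <- !duplicated(resB)
  out <- rbind(
    data.frame(partner = "A", chain_id = A$atoms$chain_id[firstA],
               residue_id = A$atoms$residue_id[firstA],
               residue_name = A$atoms$residue_name[firstA],
               mean_contribution = as.numeric(accA) / n),
    data.frame(partner = "B", chain_id = B$atoms$chain_id[firstB],
               residue_id = B$atoms$residue_id[firstB],
               residue_name = B$atoms$residue_name[firstB],
               mean_contribution = as.numeric(accB) / n))
  rownames(out) <- NULL
  attr(out, "mean_total") <- mean(poses$total)
  attr(out, "attribution") <- attribution
  out
}

#' Ligand RMSD between two poses
#'
#' Root-mean-square deviation between two placements of the smaller
#' partner (B), with the larger partner (A) superposed, i.e. with both
#' poses expressed in A's fixed frame. Computed on the exact transformed
#' coordinates of B (`rotation %*% x + displacement`), not on lattice
#' indices.
#'
#' @param pose_i,pose_j lists with elements `rotation` (3x3 matrix) and
#'   `displacement` (length-3, Angstrom).
#' @param B the smaller partner (`rigid_structure`).
#' @param A unused; accepted so both partners can be passed for clarity.
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(pose_i, pose_j, B, A = NULL) {
  x <- coords(B)
  pi_ <- sweep(x %*% t(pose_i$rotation), 2, pose_i$displacement, "+")
  pj_ <- sweep(x %*% t(pose_j$rotation), 2, pose_j$displacement, "+")
  sqrt(mean(rowSums((pi_ - pj_)^2)))
}

# n_poses x (3 n_atoms) matrix of exact B placements for a pose table
.pose_placement_matrix <- function(poses, B) {
  meta <- attr(poses, "fields_meta")
  x <- coords(B)
  out <- matrix(0, nrow = nrow(poses), ncol = 3L * nrow(x))
  for (i in seq_len(nrow(poses))) {
    m <- meta[[as.character(poses$rotation_id[i])]]
    pl <- sweep(x %*% t(m$rotation), 2,
                c(poses$dx[i], poses$dy[i], poses$dz[i]), "+")
    out[i, ] <- as.vector(pl)
  }
  out
}

#' Cluster poses by ligand RMSD (greedy single linkage)
#'
#' Starting from the lowest-energy unassigned pose, grows a cluster by
#' repeatedly absorbing every unassigned pose within the ligand-RMSD
#' cutoff of any current member, until closure; then seeds the next
#' cluster from the lowest-energy remaining pose. This partitions all
#' poses; clusters smaller than `min_size` are then discarded. The
#' representative of a cluster is its lowest-energy member.
#'
#' @param poses a `pose_table` sorted ascending by energy (as returned by
#'   [top_k_poses()]).
#' @param B the smaller partner used for ligand RMSD.
#' @param cutoff ligand RMSD cutoff in Angstrom (default 9).
#' @param min_size minimum retained cluster size (default 10).
#' @return list with `clusters` (data frame: `cluster`, `size`,
#'   `representative` pose_id, `representative_energy`), `membership`
#'   (integer vector over poses, `NA` for members of discarded clusters)
#'   and `membership_all` (the full partition before the size filter).
#' @export
cluster_poses <- function(poses, B, cutoff = 9, min_size = 10) {
  n <- nrow(poses)
  if (!n) return(list(clusters = data.frame(), membership = integer(0),
                      membership_all = integer(0)))
  P <- .pose_placement_matrix(poses, B)
  natoms <- nrow(coords(B))
  s <- rowSums(P^2)
  G <- P %*% t(P)
  d2 <- pmax(outer(s, s, "+") - 2 * G, 0) / natoms  # squared ligand RMSD
  within <- d2 <= cutoff^2
  assign_all <- rep(NA_integer_, n)
  cl <- 0L
  while (anyNA(assign_all)) {
    cl <- cl + 1L
    seedi <- which(is.na(assign_all))[1]  # poses sorted by energy
    members <- seedi
    repeat {
      cand <- which(is.na(assign_all))
      cand <- setdiff(cand, members)
      if (!length(cand)) break
      hit <- cand[colSums(within[members, cand, drop = FALSE]) > 0]
      if (!length(hit)) break
      members <- c(members, hit)
    }
    assign_all[members] <- cl
  }
  sizes <- tabulate(assign_all)
  keep <- which(sizes >= min_size)
  membership <- ifelse(assign_all %in% keep, assign_all, NA_integer_)
  clusters <- do.call(rbind, lapply(seq_along(keep), function(j) {
    members <- which(assign_all == keep[j])
    rep_i <- members[which.min(poses$total[members])]
    data.frame(cluster = j, size = length(members),
               representative = poses$pose_id[rep_i],
               representative_energy = poses$total[rep_i])
  }))
  # renumber retained clusters 1..K in order of appearance
  remap <- stats::setNames(seq_along(keep), keep)
  membership <- unname(remap[as.character(membership)])
  list(clusters = clusters %||% data.frame(),
       membership = membership, membership_all = assign_all)
}
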