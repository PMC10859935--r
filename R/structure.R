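# Rigid atomistic structures: PQR input/output, conformation slicing,
# approximate mutation, and protonation-microstate enumeration.

# Average residue masses (Da) for the 20 standard amino acids, i.e. the
# monoisotope-free mean masses of the residue (amino acid minus water).
.residue_mass <- c(
  ALA = 71.0788,  ARG = 156.1875, ASN = 114.1038, ASP = 115.0886,
  CYS = 103.1388, GLU = 129.1155, GLN = 128.1307, GLY = 57.0519,
  HIS = 137.1411, ILE = 113.1594, LEU = 113.1594, LYS = 128.1741,
  MET = 131.1926, PHE = 147.1766, PRO = 97.1167,  SER = 87.0782,
  THR = 101.1051, TRP = 186.2132, TYR = 163.1760, VAL = 99.1326
)
.water_mass <- 18.0153
.default_residue_mass <- 110.0  # fallback for non-standard residues

# Net side-chain charge (e) of the target residue in the fixed-protonation
# convention used throughout: Asp/Glu deprotonated, Lys/Arg protonated,
# His neutral by default (its charge is handled by microstate enumeration).
.sidechain_charge <- c(
  ALA = 0, ARG = +1, ASN = 0, ASP = -1, CYS = 0, GLU = -1, GLN = 0,
  GLY = 0, HIS = 0, ILE = 0, LEU = 0, LYS = +1, MET = 0, PHE = 0,
  PRO = 0, SER = 0, THR = 0, TRP = 0, TYR = 0, VAL = 0
)

.his_names <- c("HIS", "HSD", "HSE", "HSP", "HID", "HIE", "HIP")
.backbone_names <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3",
                     "HA", "HA2", "HA3", "HN")
.imidazole_names <- c("CG", "ND1", "CD2", "CE1", "NE2",
                      "HD1", "HD2", "HE1", "HE2")

#' Construct a rigid structure
#'
#' A rigid structure is an ordered set of atoms (coordinates, partial
#' charges, radii) grouped into residues; it is the rigid body entering all
#' energy and virial calculations.
#'
#' @param atoms data frame with columns `atom_name`, `residue_name`,
#'   `residue_id` (integer), `chain_id`, `x`, `y`, `z` (Angstrom),
#'   `charge` (e), `radius` (Angstrom).
#' @param molar_mass molar mass in g/mol; if `NULL`, estimated from residue
#'   composition via average residue masses (see Details).
#' @param conformation_tag one of `"open"`, `"closed"`, `"other"`.
#' @param titratable_sites data frame with columns `residue_id`, `pKa`;
#'   if `NULL`, every histidine residue is registered with pKa
#'   `default_pKa`.
#' @param default_pKa pKa assigned to auto-detected histidines (default 6.3,
#'   appropriate for a solvent-exposed imidazole).
#'
#' @details Molar mass estimation sums average residue masses over the
#'   residue composition and adds one water; residues with unrecognized
#'   names contribute 110 Da. Since only ratios of virial coefficients
#'   depend on the mass for a fixed structure, an explicit override via
#'   `molar_mass` is supported and recorded as-is.
#'
#' @return An object of class `rigid_structure`.
#' @export
rigid_structure <- function(atoms, molar_mass = NULL,
                            conformation_tag = "other",
                            titratable_sites = NULL, default_pKa = 6.3) {
  need <- c("atom_name", "residue_name", "residue_id", "chain_id",
            "x", "y", "z", "charge", "radius")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stopf("atoms is missing columns: %s",
                          paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stopf("structure has zero atoms")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stopf("non-finite atom coordinates")
  if (any(atoms$radius <= 0)) stopf("all atomic radii must be > 0")
  atoms$residue_id <- as.integer(atoms$residue_id)
  conformation_tag <- match.arg(conformation_tag, c("open", "closed", "other"))

  if (is.null(titratable_sites)) {
    his <- unique(atoms$residue_id[atoms$residue_name %in% .his_names])
    titratable_sites <- data.frame(residue_id = as.integer(his),
                                   pKa = rep(default_pKa, length(his)))
  } else {
    titratable_sites <- as.data.frame(titratable_sites)
    if (!all(c("residue_id", "pKa") %in% names(titratable_sites)))
      stopf("titratable_sites needs columns residue_id, pKa")
    bad <- setdiff(titratable_sites$residue_id, atoms$residue_id)
    if (length(bad)) stopf("titratable site(s) not in structure: %s",
                           paste(bad, collapse = ", "))
  }

  if (is.null(molar_mass)) {
    key <- paste(atoms$chain_id, atoms$residue_id)
    resnames <- atoms$residue_name[!duplicated(key)]
    m <- .residue_mass[resnames]
    m[is.na(m)] <- .default_residue_mass
    molar_mass <- sum(m) + .water_mass
  }
  if (!is.finite(molar_mass) || molar_mass <= 0)
    stopf("molar_mass must be a positive number")

  structure(list(atoms = atoms, molar_mass = molar_mass,
                 conformation_tag = conformation_tag,
                 titratable_sites = titratable_sites),
            class = "rigid_structure")
}

#' @export
print.rigid_structure <- function(x, ...) {
  cat(sprintf(
    "<rigid_structure> %d atoms, %d residues, M = %.1f g/mol, net charge %+.2f e\n",
    nrow(x$atoms), n_residues(x), x$molar_mass, sum(x$atoms$charge)))
  cat(sprintf("  conformation: %s; titratable sites: %s\n",
              x$conformation_tag,
              if (nrow(x$titratable_sites)) {
                paste(x$titratable_sites$residue_id, collapse = ", ")
              } else "none"))
  invisible(x)
}

#' Number of distinct residues in a rigid structure
#' @param s a `rigid_structure`
#' @return integer count of distinct (chain, residue id) pairs
#' @export
n_residues <- function(s) {
  length(unique(paste(s$atoms$chain_id, s$atoms$residue_id)))
}

#' Atom coordinates as a matrix
#' @param s a `rigid_structure`
#' @return numeric n x 3 matrix (Angstrom)
#' @export
coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

#' Read a PQR file
#'
#' Parses the whitespace-delimited PQR dialect: `ATOM`/`HETATM` records in
#' which the occupancy and B-factor columns of PDB are replaced by the
#' partial charge (e) and radius (Angstrom). Both the 10-field (no chain
#' identifier) and 11-field (with chain) layouts are accepted.
#'
#' @param path path to a PQR file, or a character vector of lines.
#' @inheritParams rigid_structure
#' @return A [rigid_structure()].
#' @export
read_pqr <- function(path, molar_mass = NULL, conformation_tag = "other",
                     default_pKa = 6.3) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
           else as.character(path)
  keep <- grepl("^(ATOM|HETATM)", lines)
  idx <- which(keep)
  if (!length(idx)) stopf("no ATOM/HETATM records found")
  rows <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    ln <- idx[i]
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    nt <- length(tok)
    if (nt == 10L) {
      chain <- ""
      off <- 0L
    } else if (nt == 11L) {
      chain <- tok[5]
      off <- 1L
    } else {
      stopf("line %d: expected 10 or 11 whitespace-delimited fields, got %d",
            ln, nt)
    }
    num <- suppressWarnings(as.numeric(tok[(5L + off):(10L + off)]))
    rid <- suppressWarnings(as.integer(tok[5L + off]))
    if (any(is.na(num[-1])) || is.na(rid))
      stopf("line %d: malformed numeric field", ln)
    rows[[i]] <- data.frame(atom_name = tok[3], residue_name = tok[4],
                            residue_id = rid, chain_id = chain,
                            x = num[2], y = num[3], z = num[4],
                            charge = num[5], radius = num[6])
  }
  atoms <- do.call(rbind, rows)
  rigid_structure(atoms, molar_mass = molar_mass,
                  conformation_tag = conformation_tag,
                  default_pKa = default_pKa)
}

#' Write a rigid structure to a PQR file
#'
#' @param s a `rigid_structure`
#' @param path output file path; if `NULL`, the formatted lines are returned
#'   invisibly without writing.
#' @return character vector of PQR lines, invisibly.
#' @export
write_pqr <- function(s, path = NULL) {
  a <- s$atoms
  chain <- ifelse(nzchar(a$chain_id), paste0(a$chain_id, " "), "")
  lines <- sprintf("ATOM  %5d %-4s %-4s %s%4d    %8.3f %8.3f %8.3f %8.4f %7.4f",
                   seq_len(nrow(a)), a$atom_name, a$residue_name, chain,
                   a$residue_id, a$x, a$y, a$z, a$charge, a$radius)
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Extract a residue range as a new conformation
#'
#' Keeps only atoms whose residue id lies in `[first, last]` (inclusive on
#' both ends; numbering follows the source file). Used to switch between
#' alternative conformations of the same domain, e.g. a SUMO domain with its
#' N-terminal tail bound over the binding groove ("closed") versus with the
#' tail removed ("open").
#'
#' @param s a `rigid_structure`
#' @param first,last residue id range (inclusive)
#' @param conformation_tag tag recorded on the sliced structure
#' @param molar_mass optional override; by default recomputed from the
#'   sliced residue composition.
#' @return A [rigid_structure()] restricted to the range.
#' @export
slice_conformation <- function(s, first, last, conformation_tag = "other",
                               molar_mass = NULL) {
  if (first > last) stopf("first (%s) must be <= last (%s)", first, last)
  keep <- s$atoms$residue_id >= first & s$atoms$residue_id <= last
  if (!any(keep)) stopf("residue range [%d, %d] does not intersect structure",
                        first, last)
  atoms <- s$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  ts <- s$titratable_sites
  ts <- ts[ts$residue_id >= first & ts$residue_id <= last, , drop = FALSE]
  rigid_structure(atoms, molar_mass = molar_mass,
                  conformation_tag = conformation_tag, titratable_sites = ts)
}

#' Apply an approximate point mutation
#'
#' Implements a coarse, reduced side-chain representation of a point
#' mutation: backbone atoms and C-beta are retained, the remaining
#' side-chain atoms are replaced by a single pseudo-atom placed at the old
#' side-chain centroid that carries the target residue's net side-chain
#' charge and the mean radius of the replaced atoms. This mode is intended
#' for toy structures and sensitivity checks; faithful mutants of real
#' proteins should be prepared externally (full side-chain rebuilding is
#' out of scope) and supplied as PQR inputs.
#'
#' @param s a `rigid_structure`
#' @param spec mutation string such as `"H35S"`: one-letter wild-type code,
#'   residue id, one-letter target code.
#' @param default_pKa pKa given to a histidine introduced by the mutation.
#' @return The mutated `rigid_structure`. Mutating a histidine away removes
#'   its titratable site; mutating to histidine adds one. Lys/Arg targets
#'   carry a fixed +1 side-chain charge; Asp/Glu a fixed -1.
#' @export
apply_mutation <- function(s, spec, default_pKa = 6.3) {
  m <- regmatches(spec, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", spec))[[1]]
  if (length(m) != 4L) stopf("cannot parse mutation spec '%s'", spec)
  one2three <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
                 E = "GLU", Q = "GLN", G = "GLY", H = "HIS", I = "ILE",
                 L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
                 S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  wt3 <- one2three[toupper(m[2])]
  mut3 <- one2three[toupper(m[4])]
  rid <- as.integer(m[3])
  if (is.na(mut3)) stopf("unknown target residue code '%s'", m[4])
  sel <- s$atoms$residue_id == rid
  if (!any(sel)) stopf("residue %d not present in structure", rid)
  found <- unique(s$atoms$residue_name[sel])[1]
  wt_ok <- found == wt3 || (wt3 == "HIS" && found %in% .his_names)
  if (!wt_ok) stopf("wild-type mismatch at residue %d: structure has %s, spec says %s",
                    rid, found, wt3)

  atoms <- s$atoms
  res <- atoms[sel, , drop = FALSE]
  is_bb <- res$atom_name %in% c(.backbone_names, "CB", "HB", "HB1", "HB2", "HB3")
  side <- res[!is_bb, , drop = FALSE]
  kept <- res[is_bb, , drop = FALSE]
  if (nrow(kept) == 0L) kept <- res[0, , drop = FALSE]
  kept$residue_name <- mut3
  # backbone keeps its file charges; the side-chain pseudo-atom carries the
  # target's net side-chain charge so the residue nets correctly
  if (nrow(side) > 0L && mut3 != "GLY") {
    pseudo <- data.frame(
      atom_name = "SC1", residue_name = mut3, residue_id = rid,
      chain_id = res$chain_id[1],
      x = mean(side$x), y = mean(side$y), z = mean(side$z),
      charge = unname(.sidechain_charge[mut3]),
      radius = mean(side$radius))
    newres <- rbind(kept, pseudo)
  } else if (nrow(kept) > 0L) {
    newres <- kept
  } else {
    stopf("residue %d has no retainable atoms under the reduced mutation mode",
          rid)
  }
  first <- min(which(sel)); lastidx <- max(which(sel)); na <- nrow(atoms)
  atoms <- rbind(
    if (first > 1L) atoms[seq_len(first - 1L), , drop = FALSE],
    newres,
    if (lastidx < na) atoms[(lastidx + 1L):na, , drop = FALSE])
  rownames(atoms) <- NULL

  ts <- s$titratable_sites
  ts <- ts[ts$residue_id != rid, , drop = FALSE]
  if (mut3 == "HIS") {
    ts <- rbind(ts, data.frame(residue_id = rid, pKa = default_pKa))
  }
  rigid_structure(atoms, molar_mass = NULL,
                  conformation_tag = s$conformation_tag, titratable_sites = ts)
}

#' Henderson-Hasselbalch protonated fraction
#'
#' Probability that a titratable site of acid dissociation constant `pKa`
#' is protonated at the given pH: `1 / (1 + 10^(pH - pKa))`.
#'
#' @param pH solution pH
#' @param pKa site pKa
#' @return protonated fraction in `[0, 1]`; vectorized over both arguments.
#' @export
protonated_fraction <- function(pH, pKa) {
  stopifnot(all(is.finite(pH)), all(is.finite(pKa)))
  1 / (1 + 10^(pH - pKa))
}

#' Enumerate protonation microstates
#'
#' Enumerates all `2^n` combinations of protonated/deprotonated states over
#' the structure's titratable sites (histidines by default). Each
#' microstate's weight is the product of the per-site
#' Henderson-Hasselbalch probabilities at the given pH, so weights sum
#' to 1. Each microstate carries a full per-atom charge vector in which the
#' atoms of each titratable residue are adjusted so that the residue's net
#' charge is its file value plus 1 (protonated) or plus 0 (deprotonated);
#' the +1 increment is spread over the imidazole ring atoms when present,
#' otherwise uniformly over the residue's atoms. Only the charge sums are
#' contractual; the per-atom split is a template choice.
#'
#' @param s a `rigid_structure`
#' @param pH solution pH
#' @param normalize if `TRUE` (default), each titratable residue's file
#'   charges are first shifted uniformly so the residue nets to 0 in the
#'   deprotonated state (and hence exactly +1 when protonated); set to
#'   `FALSE` to layer the protonation increment on the file charges as-is.
#' @return list of microstates; each is a list with elements `site_states`
#'   (named character vector `"protonated"`/`"deprotonated"` keyed by
#'   residue id), `weight`, and `charges` (numeric vector over all atoms).
#'   With zero titratable sites a single microstate of weight 1 carrying
#'   the file charges is returned.
#' @export
enumerate_protonation <- function(s, pH, normalize = TRUE) {
  sites <- s$titratable_sites
  n <- nrow(sites)
  base_q <- s$atoms$charge
  if (n == 0L) {
    return(list(list(site_states = character(0), weight = 1,
                     charges = base_q)))
  }
  if (normalize) {
    for (j in seq_len(n)) {
      sel <- which(s$atoms$residue_id == sites$residue_id[j])
      base_q[sel] <- base_q[sel] - sum(base_q[sel]) / length(sel)
    }
  }
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), n))[, n:1, drop = FALSE]
  fprot <- protonated_fraction(pH, sites$pKa)
  out <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    prot <- as.logical(combos[k, ])
    w <- prod(ifelse(prot, fprot, 1 - fprot))
    q <- base_q
    for (j in seq_len(n)) {
      rid <- sites$residue_id[j]
      sel <- which(s$atoms$residue_id == rid)
      ring <- sel[s$atoms$atom_name[sel] %in% .imidazole_names]
      tgt <- if (length(ring)) ring else sel
      if (prot[j]) q[tgt] <- q[tgt] + 1 / length(tgt)
    }
    out[[k]] <- list(
      site_states = stats::setNames(
        ifelse(prot, "protonated", "deprotonated"),
        as.character(sites$residue_id)),
      weight = w, charges = q)
  }
  out
}
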