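# Distance-based protein-ligand interaction classifier.
#
# Three geometric contact classes between a docked ligand and the receptor:
#   hydrogen bonds   polar (N/O) ligand atom -- polar protein atom <= 3.5 A
#   hydrophobic      ligand carbon -- side-chain carbon of an apolar residue <= 4.0 A
#   pi-stacking      ligand atom -- aromatic ring atom of PHE/TRP/TYR <= 5.5 A
# All cutoffs are inclusive. An optional angle mode adds the classical
# donor-H-acceptor >= 120 degree criterion when hydrogens are present.

AROMATIC_RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),  # OH excluded
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Interaction criteria for the contact classifier
#'
#' Bundles the distance cutoffs and residue sets used by the profiler.
#' Defaults are the screening protocol values: 3.5 A for hydrogen bonds
#' between polar (N, O) atoms, 4.0 A for hydrophobic carbon-carbon contacts
#' to PHE/TRP/TYR/LEU/ILE/VAL/ALA/MET/PRO, and 5.5 A for proximity to the
#' aromatic rings of PHE/TRP/TYR. The donor-H-acceptor angle minimum is used
#' only in angle mode.
#'
#' @param hbond_cutoff,hydrophobic_cutoff,pistack_cutoff Distance cutoffs in
#'   Angstrom (inclusive).
#' @param hbond_angle_min Minimum donor-H-acceptor angle in degrees,
#'   applied only when `angle_mode = TRUE` in the finders and hydrogens are
#'   present.
#' @param hydrophobic_residues,aromatic_residues Three-letter residue codes.
#' @return An object of class `interaction_criteria`.
#' @export
interaction_criteria <- function(hbond_cutoff = 3.5,
                                 hydrophobic_cutoff = 4.0,
                                 pistack_cutoff = 5.5,
                                 hbond_angle_min = 120,
                                 hydrophobic_residues = c(
                                   "PHE", "TRP", "TYR", "LEU", "ILE",
                                   "VAL", "ALA", "MET", "PRO"
                                 ),
                                 aromatic_residues = c("PHE", "TRP", "TYR")) {
  if (any(c(hbond_cutoff, hydrophobic_cutoff, pistack_cutoff) <= 0)) {
    abort("All distance cutoffs must be positive.")
  }
  structure(
    list(
      hbond_cutoff = hbond_cutoff, hydrophobic_cutoff = hydrophobic_cutoff,
      pistack_cutoff = pistack_cutoff, hbond_angle_min = hbond_angle_min,
      hydrophobic_residues = toupper(hydrophobic_residues),
      aromatic_residues = toupper(aromatic_residues)
    ),
    class = "interaction_criteria"
  )
}

cross_dist <- function(a, b) {
  # a: n x 3, b: m x 3 -> n x m Euclidean distances
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

contact_tibble <- function(lig, prot, dmat, cutoff, type) {
  hits <- which(dmat <= cutoff, arr.ind = TRUE)
  if (nrow(hits) == 0) {
    return(tibble::tibble(
      type = character(), ligand_serial = integer(), ligand_atom = character(),
      protein_serial = integer(), protein_atom = character(),
      resname = character(), chain = character(), resno = integer(),
      residue = character(), distance = double()
    ))
  }
  li <- hits[, 1]; pi_ <- hits[, 2]
  tibble::tibble(
    type = type,
    ligand_serial = lig$serial[li], ligand_atom = lig$name[li],
    protein_serial = prot$serial[pi_], protein_atom = prot$name[pi_],
    resname = prot$resname[pi_], chain = prot$chain[pi_],
    resno = prot$resno[pi_],
    residue = paste0(prot$resname[pi_], prot$resno[pi_]),
    distance = dmat[hits]
  )
}

xyz_mat <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

# hydrogens covalently bonded to a heavy atom (simple distance criterion)
bonded_hydrogens <- function(heavy_xyz, h_atoms, max_bond = 1.25) {
  if (nrow(h_atoms) == 0) return(integer(0))
  d <- cross_dist(matrix(heavy_xyz, nrow = 1), xyz_mat(h_atoms))
  which(d[1, ] <= max_bond)
}

angle_deg <- function(a, b, c) {
  # angle at b, degrees
  v1 <- a - b; v2 <- c - b
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Find hydrogen-bond contacts
#'
#' All (ligand N/O, protein N/O) atom pairs within the hydrogen-bond cutoff.
#' In angle mode, a pair where either partner carries a covalently bonded
#' hydrogen must additionally satisfy a donor-H-acceptor angle of at least
#' `hbond_angle_min` degrees for some such hydrogen; pairs with no hydrogens
#' present fall back to the distance-only criterion.
#'
#' @param complex A `complex_structure`.
#' @param criteria An [interaction_criteria()] object.
#' @param angle_mode Apply the angle criterion when hydrogens are present?
#' @return A contact tibble (`type == "hbond"`), one row per atom pair.
#' @export
find_hbonds <- function(complex, criteria = interaction_criteria(),
                        angle_mode = FALSE) {
  lig <- dplyr::filter(complex$ligand, .data$is_polar)
  prot <- dplyr::filter(complex$protein, .data$is_polar)
  if (nrow(lig) == 0 || nrow(prot) == 0) {
    return(contact_tibble(atom_cols(0), atom_cols(0), matrix(0, 0, 0),
      criteria$hbond_cutoff, "hbond"))
  }
  dmat <- cross_dist(xyz_mat(lig), xyz_mat(prot))
  contacts <- contact_tibble(lig, prot, dmat, criteria$hbond_cutoff, "hbond")
  if (!angle_mode || nrow(contacts) == 0) return(contacts)

  lig_h <- dplyr::filter(complex$ligand, .data$element == "H")
  prot_h <- dplyr::filter(complex$protein, .data$element == "H")
  keep <- vapply(seq_len(nrow(contacts)), function(i) {
    lat <- dplyr::filter(lig, .data$serial == contacts$ligand_serial[i])[1, ]
    pat <- dplyr::filter(prot, .data$serial == contacts$protein_serial[i])[1, ]
    lp <- c(lat$x, lat$y, lat$z); pp <- c(pat$x, pat$y, pat$z)
    lh <- bonded_hydrogens(lp, lig_h)
    ph <- bonded_hydrogens(pp, prot_h)
    if (length(lh) == 0 && length(ph) == 0) return(TRUE)  # no H info
    ok <- FALSE
    for (j in lh) {  # ligand donor -> protein acceptor
      hxyz <- as.numeric(lig_h[j, c("x", "y", "z")])
      if (angle_deg(lp, hxyz, pp) >= criteria$hbond_angle_min) ok <- TRUE
    }
    for (j in ph) {  # protein donor -> ligand acceptor
      hxyz <- as.numeric(prot_h[j, c("x", "y", "z")])
      if (angle_deg(pp, hxyz, lp) >= criteria$hbond_angle_min) ok <- TRUE
    }
    ok
  }, logical(1))
  contacts[keep, , drop = FALSE]
}

#' Find hydrophobic contacts
#'
#' Pairs a ligand carbon with a side-chain carbon of a listed hydrophobic
#' residue within the hydrophobic cutoff. Backbone carbons (C, CA) and
#' polar side-chain atoms are excluded.
#'
#' @inheritParams find_hbonds
#' @return A contact tibble (`type == "hydrophobic"`).
#' @export
find_hydrophobic <- function(complex, criteria = interaction_criteria()) {
  lig <- dplyr::filter(complex$ligand, .data$is_carbon)
  prot <- dplyr::filter(
    complex$protein,
    .data$is_carbon,
    .data$resname %in% criteria$hydrophobic_residues,
    !(.data$name %in% BACKBONE_ATOMS)
  )
  if (nrow(lig) == 0 || nrow(prot) == 0) {
    return(contact_tibble(atom_cols(0), atom_cols(0), matrix(0, 0, 0),
      criteria$hydrophobic_cutoff, "hydrophobic"))
  }
  dmat <- cross_dist(xyz_mat(lig), xyz_mat(prot))
  contact_tibble(lig, prot, dmat, criteria$hydrophobic_cutoff, "hydrophobic")
}

#' Find pi-stacking contacts
#'
#' Proximity of the ligand to the aromatic ring atoms of PHE/TRP/TYR within
#' the pi-stacking cutoff. In the default (literal) mode any ligand atom
#' counts; in strict mode only ligand atoms flagged aromatic do. No
#' ring-plane angle test is applied in either mode.
#'
#' @inheritParams find_hbonds
#' @param strict Require the ligand atom to carry the aromatic flag?
#' @return A contact tibble (`type == "pistack"`).
#' @export
find_pi_stacking <- function(complex, criteria = interaction_criteria(),
                             strict = FALSE) {
  lig <- complex$ligand
  if (strict) lig <- dplyr::filter(lig, .data$aromatic)
  prot <- dplyr::filter(complex$protein,
    .data$resname %in% criteria$aromatic_residues)
  prot <- dplyr::filter(prot, purrr::map2_lgl(
    .data$resname, .data$name,
    function(rn, nm) rn %in% names(AROMATIC_RING_ATOMS) &&
      nm %in% AROMATIC_RING_ATOMS[[rn]]
  ))
  if (nrow(lig) == 0 || nrow(prot) == 0) {
    return(contact_tibble(atom_cols(0), atom_cols(0), matrix(0, 0, 0),
      criteria$pistack_cutoff, "pistack"))
  }
  dmat <- cross_dist(xyz_mat(lig), xyz_mat(prot))
  contact_tibble(lig, prot, dmat, criteria$pistack_cutoff, "pistack")
}

sorted_residues <- function(contacts) {
  if (nrow(contacts) == 0) return(character(0))
  res <- dplyr::distinct(contacts, .data$chain, .data$resno, .data$residue)
  res <- dplyr::arrange(res, .data$chain, .data$resno)
  res$residue
}

#' Profile all protein-ligand interactions in a complex
#'
#' Runs the hydrogen-bond, hydrophobic and pi-stacking finders and
#' aggregates per-residue assignments. A residue appears once per
#' interaction type, sorted by (chain, residue number); the same residue may
#' appear under several types.
#'
#' @inheritParams find_hbonds
#' @param strict_pi Use strict (aromatic-flag) pi-stacking mode?
#' @return An object of class `interaction_profile`: a list with sorted
#'   unique `hbond_residues`, `pistack_residues`, `hydrophobic_residues`
#'   (as `NAME<number>` ids), the raw `contacts` tibble, and a `counts`
#'   tibble. Use [tidy()] for contacts and [glance()] for counts.
#' @export
profile_complex <- function(complex, criteria = interaction_criteria(),
                            angle_mode = FALSE, strict_pi = FALSE) {
  hb <- find_hbonds(complex, criteria, angle_mode = angle_mode)
  hp <- find_hydrophobic(complex, criteria)
  ps <- find_pi_stacking(complex, criteria, strict = strict_pi)
  contacts <- dplyr::bind_rows(hb, ps, hp)
  counts <- tibble::tibble(
    type = c("hbond", "pistack", "hydrophobic"),
    n_contacts = c(nrow(hb), nrow(ps), nrow(hp)),
    n_residues = c(length(sorted_residues(hb)), length(sorted_residues(ps)),
      length(sorted_residues(hp)))
  )
  structure(
    list(
      hbond_residues = sorted_residues(hb),
      pistack_residues = sorted_residues(ps),
      hydrophobic_residues = sorted_residues(hp),
      contacts = contacts,
      counts = counts,
      criteria = criteria,
      ligand_name = complex$ligand_name
    ),
    class = "interaction_profile"
  )
}

#' @export
print.interaction_profile <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = ", ") else "-"
  cat("<interaction_profile>", x$ligand_name, "\n")
  cat("  H-bond residues:     ", fmt(x$hbond_residues), "\n")
  cat("  pi-stacking residues:", fmt(x$pistack_residues), "\n")
  cat("  hydrophobic contacts:", fmt(x$hydrophobic_residues), "\n")
  invisible(x)
}

#' @export
tidy.interaction_profile <- function(x, ...) x$contacts

#' @export
glance.interaction_profile <- function(x, ...) {
  tibble::tibble(
    ligand = x$ligand_name,
    n_hbond_residues = length(x$hbond_residues),
    n_pistack_residues = length(x$pistack_residues),
    n_hydrophobic_residues = length(x$hydrophobic_residues),
    n_contacts = nrow(x$contacts)
  )
}

#' Check a profile against required reference interactions
#'
#' Verifies that a set of required hydrogen-bond residues (e.g. the anchor
#' residues of the co-crystallised reference ligand) is present in a
#' profile's hydrogen-bond list.
#'
#' @param profile An `interaction_profile`.
#' @param required Character vector of residue ids (e.g. `c("ASN458",
#'   "TRP459")`). An empty set passes vacuously.
#' @return A list with `pass` (logical) and `missing` (character vector).
#' @export
check_reference_interactions <- function(profile, required) {
  required <- toupper(required)
  missing <- setdiff(required, profile$hbond_residues)
  list(pass = length(missing) == 0, missing = missing)
}
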