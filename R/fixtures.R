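#' Flavonoid screening panel: compound fixtures
#'
#' The eight naturally occurring flavonoids of the GLUT9 screening panel, with
#' PubChem identity (CID), canonical SMILES, molecular formula, and the
#' published docking affinity against the GLUT9 urate transporter (cryo-EM
#' structure 8Y66) used as reference throughout the package. Apigenin is the
#' reference compound (co-crystallised GLUT9 ligand).
#'
#' @return A tibble with one row per compound and columns `name`, `cid`,
#'   `formula`, `smiles`, `affinity` (kcal/mol, more negative = more
#'   favourable binding).
#' @examples
#' flavonoid_compounds()
#' @export
flavonoid_compounds <- function() {
  tibble::tribble(
    ~name,         ~cid,     ~formula,    ~smiles,                                                                                              ~affinity,
    "EGCG",        65064L,   "C22H18O11", "C1[C@H]([C@H](OC2=CC(=CC(=C21)O)O)C3=CC(=C(C(=C3)O)O)O)OC(=O)C4=CC(=C(C(=C4)O)O)O",                 -9.10,
    "Chrysin",     5281607L, "C15H10O4",  "C1=CC=C(C=C1)C2=CC(=O)C3=C(C=C(C=C3O2)O)O",                                                          -8.35,
    "Apigenin",    5280443L, "C15H10O5",  "C1=CC(=CC=C1C2=CC(=O)C3=C(C=C(C=C3O2)O)O)O",                                                         -8.04,
    "Luteolin",    5280445L, "C15H10O6",  "C1=CC(=C(C=C1C2=CC(=O)C3=C(C=C(C=C3O2)O)O)O)O",                                                      -8.01,
    "Naringenin",  439246L,  "C15H12O5",  "C1[C@@H](OC2=CC(=CC(=C2C1=O)O)O)C3=CC=C(C=C3)O",                                                     -7.96,
    "Myricetin",   5281672L, "C15H10O8",  "C1=C(C=C(C(=C1O)O)O)C2=C(C(=O)C3=C(C=C(C=C3O2)O)O)O",                                                -7.84,
    "Quercetin",   5280343L, "C15H10O7",  "C1=CC(=C(C=C1C2=C(C(=O)C3=C(C=C(C=C3O2)O)O)O)O)O",                                                   -7.69,
    "Kaempferol",  5280863L, "C15H10O6",  "C1=CC(=CC=C1C2=C(C(=O)C3=C(C=C(C=C3O2)O)O)O)O",                                                      -7.67
  )
}

#' Published physicochemical reference values for the screening panel
#'
#' Reference molecular descriptors and ADMET verdicts for the eight
#' flavonoids, as published for the GLUT9 screening campaign: molecular
#' weight, Wildman-Crippen LogP, hydrogen-bond donors/acceptors, topological
#' polar surface area (Ertl), rotatable bonds, Lipinski verdict,
#' gastrointestinal absorption class, and blood-brain-barrier permeation
#' class. These are inputs for re-applying the rule engine and a regression
#' surface for the descriptor calculator.
#'
#' @return A tibble with columns `name`, `mw` (g/mol), `logp`, `hbd`, `hba`,
#'   `tpsa` (squared Angstrom), `rot_bonds`, `lipinski`, `gi_absorption`,
#'   `bbb`.
#' @export
flavonoid_reference_properties <- function() {
  tibble::tribble(
    ~name,        ~mw,    ~logp, ~hbd, ~hba, ~tpsa,  ~rot_bonds, ~lipinski, ~gi_absorption, ~bbb,
    "Apigenin",   270.24, 2.58,  3L,   5L,   90.90,  1L,         "Yes",     "High",         "No",
    "Chrysin",    254.24, 2.87,  2L,   4L,   70.67,  1L,         "Yes",     "High",         "Yes",
    "Quercetin",  302.24, 1.99,  5L,   7L,   131.36, 1L,         "Yes",     "High",         "No",
    "Kaempferol", 286.24, 2.28,  4L,   6L,   111.13, 1L,         "Yes",     "High",         "No",
    "Luteolin",   286.24, 2.28,  4L,   6L,   111.13, 1L,         "Yes",     "High",         "No",
    "Myricetin",  318.24, 1.69,  6L,   8L,   151.59, 1L,         "No (1)",  "Low",          "No",
    "Naringenin", 272.26, 2.51,  3L,   5L,   86.99,  1L,         "Yes",     "High",         "Yes",
    "EGCG",       458.38, 2.23,  8L,   11L,  197.37, 3L,         "No (2)",  "Low",          "No"
  )
}

#' Published frontier-orbital energies for the DFT-characterised compounds
#'
#' B3LYP/6-31G(d) frontier molecular-orbital energies, dipole moments and
#' total energies published for the three flavonoids carried into the
#' quantum-chemical stage of the screening campaign (EGCG, chrysin,
#' apigenin). Orbital energies are in eV and feed [koopmans_descriptors()];
#' dipole (Debye) and total energy (Hartree) are pass-through columns.
#'
#' @return A tibble with columns `compound`, `e_homo`, `e_lumo` (eV),
#'   `dipole` (Debye), `total_energy` (Hartree).
#' @export
flavonoid_orbital_energies <- function() {
  tibble::tribble(
    ~compound,  ~e_homo, ~e_lumo, ~dipole, ~total_energy,
    "EGCG",     -5.4567, -0.9123, 4.1266,  -1675.696433,
    "Chrysin",  -5.9244, -1.4348, 3.6727,  -877.990789,
    "Apigenin", -5.7215, -1.2744, 2.4038,  -953.176777
  )
}

#' Look up a packaged flavonoid by name or PubChem CID
#'
#' Resolves one of the eight packaged flavonoids by (case-insensitive) name
#' or by PubChem CID given as number or string. No network access: the
#' canonical SMILES and formulas are embedded.
#'
#' @param name_or_cid Compound name (e.g. `"EGCG"`) or PubChem CID
#'   (e.g. `5280443` or `"5280443"`).
#' @return A one-row tibble with columns `name`, `cid`, `formula`, `smiles`,
#'   `affinity`.
#' @examples
#' load_ligand_fixture("EGCG")
#' load_ligand_fixture(5280443)
#' @export
load_ligand_fixture <- function(name_or_cid) {
  stopifnot(length(name_or_cid) == 1)
  panel <- flavonoid_compounds()
  key <- trimws(as.character(name_or_cid))
  hit <- if (grepl("^[0-9]+$", key)) {
    dplyr::filter(panel, .data$cid == as.integer(key))
  } else {
    dplyr::filter(panel, tolower(.data$name) == tolower(key))
  }
  if (nrow(hit) != 1) {
    abort(paste0(
      "Unknown compound '", key, "'. Known fixtures: ",
      paste(panel$name, collapse = ", "),
      " (CIDs ", paste(panel$cid, collapse = ", "), ")."
    ))
  }
  hit
}
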