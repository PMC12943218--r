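# Molecular descriptors and the rule-based ADMET engine.
#
# Descriptor sources: molecular weight from the formula with IUPAC standard
# atomic weights; LogP (Wildman-Crippen), TPSA (Ertl) and H-bond donor
# counts from Open Babel via ChemmineOB; H-bond acceptors as the N+O atom
# count (Lipinski's original definition); rotatable bonds by the common
# non-ring single bond between two non-terminal heavy atoms SMARTS.

ATOMIC_WEIGHTS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904, B = 10.81,
  Si = 28.085, Na = 22.990, K = 39.098, Mg = 24.305, Ca = 40.078,
  Fe = 55.845, Zn = 65.38, Se = 78.971
)

parse_formula <- function(formula) {
  formula <- gsub("[ _]", "", formula)
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula) || length(toks) == 0) {
    abort(paste0("Cannot parse molecular formula '", formula, "'."))
  }
  el <- sub("[0-9]*$", "", toks)
  n <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", toks)))
  n[is.na(n)] <- 1L
  unknown <- setdiff(el, names(ATOMIC_WEIGHTS))
  if (length(unknown) > 0) {
    abort(paste0("Unknown element symbol(s) in formula '", formula, "': ",
      paste(unknown, collapse = ", ")))
  }
  tapply(n, el, sum)
}

#' Molecular weight from a molecular formula
#'
#' Sums IUPAC standard atomic weights over an element-count formula such as
#' `"C22H18O11"`. Values are exact sums; round at presentation (the
#' conventional two decimals) if needed.
#'
#' @param formula Character vector of molecular formulas.
#' @return Numeric vector of molecular weights in g/mol.
#' @examples
#' mw_from_formula("C15H10O5") # apigenin, 270.24
#' @export
mw_from_formula <- function(formula) {
  vapply(formula, function(f) {
    counts <- parse_formula(f)
    sum(ATOMIC_WEIGHTS[names(counts)] * counts)
  }, double(1), USE.NAMES = FALSE)
}

# ChemmineOB's list(source=, format=) convenience interface is unreliable;
# everything goes through forEachMol with an explicit OBMol ref.
with_obmol <- function(smiles, fn) {
  ChemmineOB::forEachMol("SMILES", smiles, fn)[[1]]
}

ROTATABLE_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

ob_descriptors <- function(smiles) {
  props <- tryCatch(
    with_obmol(smiles, function(m) ChemmineOB::prop_OB(m)),
    error = function(e) NULL
  )
  if (is.null(props) || !nzchar(props$formula) || props$MW <= 0) {
    abort(paste0("Unparsable SMILES: '", smiles, "'."))
  }
  rot <- with_obmol(smiles, function(m) {
    ChemmineOB::smartsSearch_OB(list(m), ROTATABLE_SMARTS, uniqueMatches = TRUE)
  })
  list(
    formula = props$formula, logp = props$logP, tpsa = props$TPSA,
    hbd = as.integer(props$HBD), rot_bonds = as.integer(rot)
  )
}

n_plus_o_count <- function(formula) {
  vapply(formula, function(f) {
    counts <- parse_formula(f)
    as.integer(sum(counts[names(counts) %in% c("N", "O")]))
  }, integer(1), USE.NAMES = FALSE)
}

#' Compute molecular descriptors from SMILES
#'
#' For each molecule: molecular weight (from the formula, IUPAC weights),
#' Wildman-Crippen LogP, H-bond donors (O-H/N-H count), H-bond acceptors
#' (N+O atom count), Ertl topological polar surface area, and rotatable
#' bonds (non-ring single bonds between non-terminal heavy atoms).
#'
#' @param molecules A character vector of SMILES, or a data frame with a
#'   `smiles` column (and optionally `name`), e.g. [flavonoid_compounds()]
#'   or [load_ligand_fixture()] output.
#' @return A tibble with columns `name`, `smiles`, `formula`, `mw`, `logp`,
#'   `hbd`, `hba`, `tpsa`, `rot_bonds`.
#' @examples
#' \donttest{
#' compute_descriptors(load_ligand_fixture("chrysin"))
#' }
#' @export
compute_descriptors <- function(molecules) {
  if (is.character(molecules)) {
    molecules <- tibble::tibble(name = molecules, smiles = molecules)
  }
  if (!"smiles" %in% names(molecules)) {
    abort("`molecules` must have a `smiles` column or be a SMILES character vector.")
  }
  if (!"name" %in% names(molecules)) molecules$name <- molecules$smiles
  purrr::map2_dfr(molecules$name, molecules$smiles, function(nm, smi) {
    d <- tryCatch(ob_descriptors(smi), error = function(e) {
      abort(paste0("Descriptor computation failed for '", nm, "': ",
        conditionMessage(e)))
    })
    tibble::tibble(
      name = nm, smiles = smi, formula = d$formula,
      mw = mw_from_formula(d$formula), logp = d$logp, hbd = d$hbd,
      hba = n_plus_o_count(d$formula), tpsa = d$tpsa,
      rot_bonds = d$rot_bonds
    )
  })
}

#' Count Lipinski rule-of-five violations
#'
#' Number of the four oral drug-likeness criteria violated (strict
#' inequalities): MW > 500 g/mol, LogP > 5, HBD > 5, HBA > 10.
#'
#' @param d A data frame with columns `mw`, `logp`, `hbd`, `hba` (e.g. from
#'   [compute_descriptors()]).
#' @return Integer vector of violation counts, one per row.
#' @export
count_lipinski_violations <- function(d) {
  stopifnot(all(c("mw", "logp", "hbd", "hba") %in% names(d)))
  as.integer((d$mw > 500) + (d$logp > 5) + (d$hbd > 5) + (d$hba > 10))
}

#' Classify gastrointestinal absorption from TPSA
#'
#' `"High"` when TPSA is at most 140 squared Angstrom (inclusive), `"Low"`
#' otherwise.
#'
#' @param tpsa Numeric vector of topological polar surface areas.
#' @return Character vector, `"High"` or `"Low"`.
#' @export
classify_gi_absorption <- function(tpsa) {
  stopifnot(all(tpsa >= 0))
  ifelse(tpsa <= 140, "High", "Low")
}

#' Classify blood-brain-barrier permeation
#'
#' `"Yes"` when both TPSA is at most 90 squared Angstrom and MW is at most
#' 450 g/mol (both boundaries inclusive), `"No"` otherwise.
#'
#' @param tpsa,mw Numeric vectors.
#' @return Character vector, `"Yes"` or `"No"`.
#' @export
classify_bbb <- function(tpsa, mw) {
  ifelse(tpsa <= 90 & mw <= 450, "Yes", "No")
}

#' Build the full descriptor + ADMET verdict table
#'
#' One row per molecule with all descriptors and rule verdicts. The
#' `lipinski` label is `"Yes"` for zero violations and `"No (n)"`
#' otherwise; the raw count is kept in `lipinski_violations` so the looser
#' at-most-one-violation convention is also recoverable.
#'
#' @param molecules Character vector of fixture names/CIDs or SMILES, or a
#'   data frame with `name` and `smiles` columns. Fixture names/CIDs are
#'   resolved via [load_ligand_fixture()].
#' @return A tibble with columns `compound`, `mw`, `logp`, `hbd`, `hba`,
#'   `tpsa`, `rot_bonds`, `lipinski_violations`, `lipinski`,
#'   `gi_absorption`, `bbb`.
#' @export
build_admet_table <- function(molecules) {
  if (is.character(molecules)) {
    known <- c(tolower(flavonoid_compounds()$name),
      as.character(flavonoid_compounds()$cid))
    molecules <- purrr::map_dfr(molecules, function(m) {
      if (tolower(trimws(m)) %in% known) load_ligand_fixture(m)
      else tibble::tibble(name = m, smiles = m)
    })
  }
  if (nrow(molecules) == 0) {
    return(tibble::tibble(
      compound = character(), mw = double(), logp = double(),
      hbd = integer(), hba = integer(), tpsa = double(),
      rot_bonds = integer(), lipinski_violations = integer(),
      lipinski = character(), gi_absorption = character(), bbb = character()
    ))
  }
  d <- compute_descriptors(molecules)
  admet_verdicts(dplyr::rename(d, compound = "name"))
}

#' Apply the ADMET rule engine to a descriptor table
#'
#' Adds `lipinski_violations`, `lipinski`, `gi_absorption` and `bbb`
#' columns to an existing descriptor table. Useful for re-applying the
#' rules to externally computed (e.g. published) descriptor values.
#'
#' @param d A data frame with columns `mw`, `logp`, `hbd`, `hba`, `tpsa`
#'   (and optionally `compound`/`name`).
#' @return The input tibble with the four verdict columns appended.
#' @export
admet_verdicts <- function(d) {
  viol <- count_lipinski_violations(d)
  dplyr::mutate(
    tibble::as_tibble(d),
    lipinski_violations = viol,
    lipinski = ifelse(viol == 0, "Yes", paste0("No (", viol, ")")),
    gi_absorption = classify_gi_absorption(.data$tpsa),
    bbb = classify_bbb(.data$tpsa, .data$mw)
  )
}
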