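# Conceptual-DFT global reactivity descriptors from frontier-orbital
# energies via Koopmans' theorem:
#   I = -E(HOMO)        ionization potential
#   A = -E(LUMO)        electron affinity
#   chi = (I + A) / 2   electronegativity
#   eta = (I - A) / 2   chemical hardness
#   S = 1 / (2 eta)     chemical softness
#   omega = chi^2/(2 eta) electrophilicity index
#   gap = E(LUMO) - E(HOMO) = 2 eta

HARTREE_TO_EV <- 27.211386  # CODATA

#' Convert Hartree to electronvolt
#'
#' @param e Numeric vector of energies in Hartree.
#' @return Energies in eV (1 Hartree = 27.211386 eV).
#' @export
hartree_to_ev <- function(e) {
  stopifnot(all(is.finite(e)))
  e * HARTREE_TO_EV
}

#' Koopmans-theorem global reactivity descriptors
#'
#' Derives ionization potential, electron affinity, electronegativity,
#' chemical hardness, softness, electrophilicity index and the HOMO-LUMO
#' gap from frontier-orbital energies (eV). Values are exact; rounding is
#' left to presentation ([build_reactivity_table()] rounds to 4 decimals).
#'
#' @param orbitals A data frame with columns `e_homo` and `e_lumo` in eV
#'   (and optionally `compound` plus pass-through columns), e.g.
#'   [flavonoid_orbital_energies()].
#' @return The input tibble with columns `i`, `a`, `chi`, `eta`,
#'   `softness` (1/eV), `omega` and `gap` appended.
#' @examples
#' koopmans_descriptors(flavonoid_orbital_energies())
#' @export
koopmans_descriptors <- function(orbitals) {
  stopifnot(all(c("e_homo", "e_lumo") %in% names(orbitals)))
  orbitals <- tibble::as_tibble(orbitals)
  if (any(orbitals$e_lumo < orbitals$e_homo)) {
    warn("e_lumo below e_homo for at least one compound; check orbital assignment.")
  }
  i <- -orbitals$e_homo
  a <- -orbitals$e_lumo
  eta <- (i - a) / 2
  if (any(eta == 0)) {
    abort("Degenerate HOMO-LUMO gap (eta = 0): softness and electrophilicity undefined.")
  }
  chi <- (i + a) / 2
  dplyr::mutate(orbitals,
    i = i, a = a, chi = chi, eta = eta,
    softness = 1 / (2 * eta), omega = chi^2 / (2 * eta),
    gap = .data$e_lumo - .data$e_homo
  )
}

#' Build the reactivity summary table (parameters x compounds)
#'
#' Produces the conventional wide layout for reporting DFT-derived
#' reactivity: one row per parameter (with unit), one column per compound,
#' values rounded to 4 decimals.
#'
#' @param orbitals As for [koopmans_descriptors()]; a `compound` column is
#'   required here. Optional `dipole` (Debye) and `total_energy` (Hartree)
#'   columns are passed through as extra rows.
#' @return A tibble with columns `parameter`, `unit`, then one column per
#'   compound. An empty input yields the header-only (zero-compound) table.
#' @export
build_reactivity_table <- function(orbitals) {
  params <- tibble::tribble(
    ~key,            ~parameter,                    ~unit,
    "total_energy",  "Total Energy",                "Hartree",
    "dipole",        "Dipole Moment",               "Debye",
    "e_homo",        "E(HOMO)",                     "eV",
    "e_lumo",        "E(LUMO)",                     "eV",
    "gap",           "HOMO-LUMO Gap (dE)",          "eV",
    "i",             "Ionization Potential (I)",    "eV",
    "a",             "Electron Affinity (A)",       "eV",
    "chi",           "Electronegativity (chi)",     "eV",
    "eta",           "Chemical Hardness (eta)",     "eV",
    "softness",      "Chemical Softness (S)",       "1/eV",
    "omega",         "Electrophilicity Index (omega)", "eV"
  )
  if (is.null(orbitals) || nrow(orbitals) == 0) {
    return(tibble::tibble(parameter = params$parameter, unit = params$unit))
  }
  stopifnot("compound" %in% names(orbitals))
  desc <- koopmans_descriptors(orbitals)
  keys <- intersect(params$key, names(desc))
  long <- tidyr::pivot_longer(
    dplyr::select(desc, "compound", dplyr::all_of(keys)),
    -"compound", names_to = "key", values_to = "value"
  )
  long$value <- round(long$value, 4)
  wide <- tidyr::pivot_wider(long, names_from = "compound", values_from = "value")
  out <- dplyr::inner_join(params, wide, by = "key")
  dplyr::select(out, -"key")
}

#' Read frontier-orbital energies from CSV
#'
#' Reads the documented key-value layout: columns `compound`, `e_homo_ev`,
#' `e_lumo_ev` and optionally `dipole_debye`, `total_energy_hartree`.
#' Quantum-chemistry log parsing is out of scope; export this CSV from the
#' QM package of choice.
#'
#' @param path CSV file path.
#' @return A tibble with columns `compound`, `e_homo`, `e_lumo` and any
#'   optional pass-through columns renamed to `dipole`, `total_energy`.
#' @export
read_orbitals_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("compound", "e_homo_ev", "e_lumo_ev")
  if (!all(need %in% names(d))) {
    abort(paste0("Orbital CSV must have columns: ", paste(need, collapse = ", ")))
  }
  d <- dplyr::rename(d, e_homo = "e_homo_ev", e_lumo = "e_lumo_ev")
  if ("dipole_debye" %in% names(d)) d <- dplyr::rename(d, dipole = "dipole_debye")
  if ("total_energy_hartree" %in% names(d)) {
    d <- dplyr::rename(d, total_energy = "total_energy_hartree")
  }
  d
}
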