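# Fixed-column PDB / PDBQT readers and writers.
#
# Atom records travel as tibbles with one row per atom:
#   serial, name, resname, chain, resno, x, y, z, element,
#   is_polar (element N/O), is_carbon, aromatic (ligand-side flag),
#   charge and ad_type (PDBQT extras, retained but unused by the profiler).
#
# A complex is a list(protein, ligand, ligand_name) of such tibbles
# (class "complex_structure"); a multi-MODEL file becomes a trajectory:
# list(topology = complex, coords = array(frames x atoms x 3), times).

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)
WATER_NAMES <- c("HOH", "WAT", "H2O", "DOD", "TIP", "SOL")

atom_cols <- function(n = 0) {
  tibble::tibble(
    serial = integer(n), name = character(n), resname = character(n),
    chain = character(n), resno = integer(n),
    x = double(n), y = double(n), z = double(n),
    element = character(n), is_polar = logical(n), is_carbon = logical(n),
    aromatic = logical(n), charge = double(n), ad_type = character(n)
  )
}

# element from columns 77-78 when present, else from the atom name
infer_element <- function(element_field, name) {
  el <- toupper(trimws(element_field))
  fallback <- toupper(trimws(name))
  fallback <- sub("^[0-9']+", "", fallback)
  two <- substr(fallback, 1, 2)
  guess <- ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "SE"),
    two, substr(fallback, 1, 1)
  )
  ifelse(el == "", guess, el)
}

parse_coord <- function(txt, lines_idx, field, source_lines) {
  val <- suppressWarnings(as.numeric(trimws(txt)))
  bad <- which(is.na(val))
  if (length(bad) > 0) {
    i <- bad[1]
    abort(paste0(
      "Malformed ", field, "-coordinate field on line ", lines_idx[i],
      ": '", trimws(txt[i]), "' (", substr(source_lines[lines_idx[i]], 1, 30), "...)"
    ))
  }
  val
}

parse_atom_lines <- function(lines, idx, pdbqt = FALSE) {
  rec <- lines[idx]
  altloc <- substr(rec, 17, 17)
  keep <- altloc %in% c(" ", "A", "")
  rec <- rec[keep]
  idx <- idx[keep]
  if (length(rec) == 0) return(atom_cols(0))
  serial <- suppressWarnings(as.integer(trimws(substr(rec, 7, 11))))
  serial[is.na(serial)] <- seq_len(sum(is.na(serial)))
  name <- trimws(substr(rec, 13, 16))
  resname <- toupper(trimws(substr(rec, 18, 20)))
  chain <- substr(rec, 22, 22)
  chain[chain == " "] <- "A"
  resno <- suppressWarnings(as.integer(trimws(substr(rec, 23, 26))))
  resno[is.na(resno)] <- 0L
  x <- parse_coord(substr(rec, 31, 38), idx, "x", lines)
  y <- parse_coord(substr(rec, 39, 46), idx, "y", lines)
  z <- parse_coord(substr(rec, 47, 54), idx, "z", lines)
  charge <- rep(NA_real_, length(rec))
  ad_type <- rep(NA_character_, length(rec))
  if (pdbqt) {
    charge <- suppressWarnings(as.numeric(trimws(substr(rec, 67, 76))))
    ad_type <- trimws(substr(rec, 78, 79))
  }
  element <- infer_element(substr(rec, 77, 78), name)
  if (pdbqt) {
    # AutoDock types carry the element more reliably than cols 77-78
    el_from_type <- toupper(sub("[^A-Za-z].*$", "", ad_type))
    el_from_type[el_from_type %in% c("A",  "")] <- NA  # A = aromatic carbon
    element <- ifelse(trimws(substr(rec, 77, 78)) == "" & !is.na(el_from_type) &
      el_from_type %in% c("C", "N", "O", "S", "P", "H", "F", "CL", "BR", "I"),
    el_from_type, element
    )
    element[toupper(ad_type) == "A"] <- "C"
  }
  tibble::tibble(
    serial = serial, name = name, resname = resname, chain = chain,
    resno = resno, x = x, y = y, z = z, element = element,
    is_polar = element %in% c("N", "O"),
    is_carbon = element == "C",
    aromatic = if (pdbqt) toupper(ad_type) == "A" else rep(FALSE, length(rec)),
    charge = charge, ad_type = ad_type
  )
}

split_protein_ligand <- function(atoms, records) {
  is_water <- atoms$resname %in% WATER_NAMES
  atoms <- atoms[!is_water, , drop = FALSE]
  records <- records[!is_water]
  is_ligand <- records == "HETATM" & !(atoms$resname %in% STANDARD_AA)
  list(
    protein = atoms[!is_ligand, , drop = FALSE],
    ligand = atoms[is_ligand, , drop = FALSE]
  )
}

#' Construct a protein-ligand complex
#'
#' Bundles a protein atom table and a ligand atom table (both in Angstrom
#' coordinates) into a `complex_structure`, the substrate of the
#' interaction profiler.
#'
#' @param protein,ligand Atom tibbles as produced by [read_pdb()] (columns
#'   `serial`, `name`, `resname`, `chain`, `resno`, `x`, `y`, `z`,
#'   `element`, ...).
#' @param ligand_name Name of the ligand molecule.
#' @return An object of class `complex_structure`.
#' @export
new_complex <- function(protein, ligand, ligand_name = "LIG") {
  for (tb in list(protein, ligand)) {
    stopifnot(all(c("name", "resname", "x", "y", "z", "element") %in% names(tb)))
  }
  if (!all(is.finite(as.matrix(ligand[, c("x", "y", "z")]))) ||
    !all(is.finite(as.matrix(protein[, c("x", "y", "z")])))) {
    abort("Non-finite coordinates in complex.")
  }
  structure(
    list(protein = tibble::as_tibble(protein),
         ligand = tibble::as_tibble(ligand),
         ligand_name = ligand_name),
    class = "complex_structure"
  )
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("<complex_structure> protein:", nrow(x$protein), "atoms in",
    dplyr::n_distinct(paste(x$protein$chain, x$protein$resno)), "residues;",
    "ligand:", x$ligand_name, "with", nrow(x$ligand), "atoms\n")
  invisible(x)
}

read_source_lines <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else if (length(source) == 1 && grepl("\n", source)) {
    strsplit(source, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(source)
  }
}

#' Read a PDB file (single-model complex or multi-model trajectory)
#'
#' Fixed-column parsing of ATOM/HETATM records. HETATM records whose residue
#' name is not one of the twenty standard amino acids become ligand atoms;
#' waters are dropped. Alternate locations keep altLoc ' '/'A' only.
#' MODEL/ENDMDL blocks delimit trajectory frames: a file with more than one
#' MODEL yields a trajectory whose topology is the first frame.
#'
#' @param source File path, a single string with embedded newlines, or a
#'   character vector of lines.
#' @param dt Time step between frames in ps (trajectories only).
#' @param ligand_name Ligand name for the resulting complex.
#' @return A `complex_structure`, or a `trajectory` for multi-model input.
#' @export
read_pdb <- function(source, dt = 20, ligand_name = "LIG") {
  lines <- read_source_lines(source)
  rectype <- substr(lines, 1, 6)
  is_atom <- rectype %in% c("ATOM  ", "HETATM") | substr(lines, 1, 4) == "ATOM"
  model_starts <- which(trimws(rectype) == "MODEL")
  n_models <- length(model_starts)

  if (n_models <= 1) {
    idx <- which(is_atom)
    if (length(idx) == 0) abort("Empty input: no ATOM/HETATM records found.")
    atoms <- parse_atom_lines(lines, idx)
    records <- trimws(substr(lines[idx], 1, 6))
    records <- records[substr(lines[idx], 17, 17) %in% c(" ", "A", "")]
    parts <- split_protein_ligand(atoms, records)
    return(new_complex(parts$protein, parts$ligand, ligand_name))
  }

  model_ends <- which(trimws(rectype) %in% c("ENDMDL", "END   ") |
    trimws(lines) == "ENDMDL")
  frames <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    from <- model_starts[m]
    to <- c(model_starts, length(lines) + 1)[m + 1] - 1
    idx <- which(is_atom & seq_along(lines) >= from & seq_along(lines) <= to)
    if (length(idx) == 0) abort(paste0("MODEL block ", m, " contains no atoms."))
    atoms <- parse_atom_lines(lines, idx)
    records <- trimws(substr(lines[idx], 1, 6))
    records <- records[substr(lines[idx], 17, 17) %in% c(" ", "A", "")]
    frames[[m]] <- list(atoms = atoms, records = records)
  }
  n_atoms <- vapply(frames, function(f) nrow(f$atoms), integer(1))
  if (length(unique(n_atoms)) != 1) {
    abort("MODEL blocks differ in atom count; cannot build a trajectory.")
  }
  parts <- split_protein_ligand(frames[[1]]$atoms, frames[[1]]$records)
  topo <- new_complex(parts$protein, parts$ligand, ligand_name)
  keep <- !(frames[[1]]$atoms$resname %in% WATER_NAMES)
  is_lig <- frames[[1]]$records[keep] == "HETATM" &
    !(frames[[1]]$atoms$resname[keep] %in% STANDARD_AA)
  ord <- c(which(!is_lig), which(is_lig))  # protein block then ligand block
  coords <- array(NA_real_, dim = c(n_models, sum(keep), 3))
  for (m in seq_len(n_models)) {
    xyz <- as.matrix(frames[[m]]$atoms[keep, c("x", "y", "z")])
    coords[m, , ] <- xyz[ord, , drop = FALSE]
  }
  new_trajectory(topo, coords, times = (seq_len(n_models) - 1) * dt)
}

#' Construct a trajectory object
#'
#' @param topology A `complex_structure` (ligand table may be empty). Atom
#'   order in `coords` is the protein block followed by the ligand block.
#' @param coords Numeric array `frames x atoms x 3`, Angstrom.
#' @param times Frame times in ps, strictly increasing.
#' @return An object of class `trajectory`.
#' @export
new_trajectory <- function(topology, coords, times = NULL) {
  stopifnot(inherits(topology, "complex_structure"), length(dim(coords)) == 3)
  n_atoms <- nrow(topology$protein) + nrow(topology$ligand)
  if (dim(coords)[2] != n_atoms) {
    abort(paste0("coords has ", dim(coords)[2], " atoms; topology has ", n_atoms, "."))
  }
  if (is.null(times)) times <- (seq_len(dim(coords)[1]) - 1) * 20
  if (length(times) != dim(coords)[1] || any(diff(times) <= 0)) {
    abort("times must match frame count and be strictly increasing.")
  }
  structure(list(topology = topology, coords = coords, times = as.numeric(times)),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", dim(x$coords)[1], "frames x", dim(x$coords)[2], "atoms,",
    "t =", x$times[1], "..", x$times[length(x$times)], "ps\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

format_pdb_line <- function(record, serial, name, resname, chain, resno,
                            x, y, z, element) {
  nm <- ifelse(nchar(name) < 4, paste0(" ", name), name)
  sprintf(
    "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    record, serial, nm, resname, chain, resno, x, y, z, 1.00, 0.00, element
  )
}

#' Write a complex (or trajectory) to PDB format
#'
#' Ligand atoms are written as HETATM records; a trajectory is written as
#' MODEL/ENDMDL blocks. Coordinates are written to three decimals.
#'
#' @param x A `complex_structure` or `trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  complex_lines <- function(cx, coords = NULL) {
    atoms <- dplyr::bind_rows(
      dplyr::mutate(cx$protein, .record = "ATOM"),
      dplyr::mutate(cx$ligand, .record = "HETATM")
    )
    if (!is.null(coords)) {
      atoms$x <- coords[, 1]; atoms$y <- coords[, 2]; atoms$z <- coords[, 3]
    }
    format_pdb_line(atoms$.record, atoms$serial, atoms$name, atoms$resname,
      atoms$chain, atoms$resno, atoms$x, atoms$y, atoms$z, atoms$element)
  }
  if (inherits(x, "trajectory")) {
    out <- unlist(lapply(seq_len(n_frames(x)), function(m) {
      c(sprintf("MODEL %8d", m), complex_lines(x$topology, x$coords[m, , ]), "ENDMDL")
    }))
  } else {
    out <- complex_lines(x)
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Read docked poses from AutoDock Vina PDBQT output
#'
#' Parses the Vina output dialect: MODEL blocks each carrying a
#' `REMARK VINA RESULT:` line whose first numeric field is the binding
#' affinity in kcal/mol. Rank is order of appearance. Partial charges and
#' AutoDock atom types are parsed and retained.
#'
#' @param source File path, string, or character vector of lines.
#' @return A tibble with columns `rank`, `affinity` (kcal/mol) and a
#'   list-column `ligand_atoms` of atom tibbles. Empty input yields a
#'   zero-row tibble.
#' @export
read_pdbqt_poses <- function(source) {
  lines <- read_source_lines(source)
  starts <- which(grepl("^MODEL", lines))
  empty <- tibble::tibble(rank = integer(), affinity = double(),
    ligand_atoms = list())
  if (length(starts) == 0) return(empty)
  ends <- c(starts[-1] - 1, length(lines))
  rows <- purrr::map(seq_along(starts), function(m) {
    block <- lines[starts[m]:ends[m]]
    res_line <- grep("REMARK VINA RESULT:", block, value = TRUE)
    if (length(res_line) == 0) {
      abort(paste0("MODEL ", m, " has no 'REMARK VINA RESULT:' line."))
    }
    nums <- suppressWarnings(as.numeric(strsplit(
      trimws(sub(".*REMARK VINA RESULT:", "", res_line[1])), "\\s+")[[1]]))
    if (length(nums) == 0 || is.na(nums[1])) {
      abort(paste0("MODEL ", m, ": could not parse affinity from VINA RESULT line."))
    }
    idx <- which(grepl("^(ATOM|HETATM)", block))
    atoms <- if (length(idx)) parse_atom_lines(block, idx, pdbqt = TRUE) else atom_cols(0)
    tibble::tibble(rank = m, affinity = nums[1], ligand_atoms = list(atoms))
  })
  dplyr::bind_rows(rows)
}

#' Select the best docked pose
#'
#' Returns the pose with the lowest (most negative, i.e. most favourable)
#' binding affinity; ties are broken by the lowest rank.
#'
#' @param poses Pose tibble from [read_pdbqt_poses()] (columns `rank`,
#'   `affinity`, ...).
#' @return The selected one-row pose tibble.
#' @export
select_best_pose <- function(poses) {
  if (!is.data.frame(poses) || nrow(poses) == 0) {
    abort("No poses supplied: cannot select a best pose from an empty set.")
  }
  dplyr::slice(dplyr::arrange(poses, .data$affinity, .data$rank), 1)
}
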