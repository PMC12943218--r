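# Trajectory analysis metrics: Kabsch superposition, backbone RMSD series,
# per-residue RMSF, intermolecular hydrogen-bond persistence, and
# Shrake-Rupley solvent-accessible surface area.

BONDI_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98
)

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of a mobile coordinate set onto a reference
#' via SVD, constrained to a proper rotation (determinant +1).
#'
#' @param mobile,reference Numeric matrices, n x 3, equal n >= 3.
#' @return A list with `rotation` (3 x 3, apply as `mobile %*% rotation`),
#'   `translation` (length 3), and `rmsd` (Angstrom) -- the least-squares
#'   minimum over all rigid transforms.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3 || ncol(reference) != 3) {
    abort("mobile and reference must be n x 3 matrices with equal n.")
  }
  if (nrow(mobile) < 3) abort("At least 3 points are required for superposition.")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  p <- sweep(mobile, 2, cm); q <- sweep(reference, 2, cr)
  h <- crossprod(p, q)
  sv <- svd(h)
  # rank < 2 (collinear points) leaves the rotation underdetermined
  if (sum(sv$d > max(sv$d) * 1e-8) < 2) {
    abort("Degenerate (collinear) point set: superposition is not unique.")
  }
  d <- sign(det(sv$u) * det(sv$v))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  aligned <- p %*% rot
  rmsd <- sqrt(mean(rowSums((aligned - q)^2)))
  list(rotation = rot, translation = cr - as.numeric(cm %*% rot), rmsd = rmsd)
}

backbone_indices <- function(traj) {
  prot <- traj$topology$protein
  idx <- which(prot$name %in% c("N", "CA", "C", "O"))
  if (length(idx) == 0) idx <- seq_len(nrow(prot))
  idx  # protein block comes first in the coords array
}

calpha_indices <- function(traj) {
  prot <- traj$topology$protein
  idx <- which(prot$name == "CA")
  if (length(idx) == 0) {
    # fall back to one atom per residue (first atom)
    idx <- which(!duplicated(paste(prot$chain, prot$resno)))
  }
  idx
}

#' Backbone RMSD time series
#'
#' Per-frame root-mean-square deviation of the selected atoms from the
#' first frame, after optimal (Kabsch) superposition of each frame onto it.
#'
#' @param traj A `trajectory`.
#' @param selection Integer atom indices into the trajectory's atom order
#'   (protein block then ligand block). Default: protein backbone
#'   (N, CA, C, O) atoms.
#' @param units `"angstrom"` (default) or `"nm"`.
#' @return A tibble with columns `time` (ps), `value`, `metric`.
#' @export
rmsd_series <- function(traj, selection = NULL, units = c("angstrom", "nm")) {
  units <- match.arg(units)
  if (is.null(selection)) selection <- backbone_indices(traj)
  if (length(selection) == 0) abort("Empty atom selection for RMSD.")
  ref <- traj$coords[1, selection, , drop = TRUE]
  vals <- vapply(seq_len(n_frames(traj)), function(m) {
    kabsch_superpose(traj$coords[m, selection, , drop = TRUE], ref)$rmsd
  }, double(1))
  if (units == "nm") vals <- vals / 10
  tibble::tibble(time = traj$times, value = vals,
    metric = paste0("rmsd_", units))
}

#' Per-residue RMSF profile
#'
#' Root-mean-square fluctuation of one atom per residue (C-alpha by
#' default) about the mean structure. Frames are first superposed onto the
#' first frame, the mean structure is computed, and frames are re-aligned
#' onto the mean (one pass) before the fluctuation is measured.
#'
#' @param traj A `trajectory`.
#' @param selection Integer atom indices (one per residue); default
#'   C-alpha atoms.
#' @param units `"angstrom"` or `"nm"`.
#' @return A tibble with columns `chain`, `resno`, `resname`, `atom`,
#'   `value` (RMSF), `metric`.
#' @export
rmsf_profile <- function(traj, selection = NULL, units = c("angstrom", "nm")) {
  units <- match.arg(units)
  if (is.null(selection)) selection <- calpha_indices(traj)
  if (length(selection) == 0) abort("Empty atom selection for RMSF.")
  nf <- n_frames(traj)
  atoms <- dplyr::bind_rows(traj$topology$protein, traj$topology$ligand)[selection, ]
  if (nf == 1) {
    warn("Single-frame trajectory: RMSF is identically zero.")
    return(tibble::tibble(chain = atoms$chain, resno = atoms$resno,
      resname = atoms$resname, atom = atoms$name, value = 0,
      metric = paste0("rmsf_", units)))
  }
  sel_coords <- array(traj$coords[, selection, , drop = FALSE],
    dim = c(nf, length(selection), 3))
  align_to <- function(coords, ref) {
    for (m in seq_len(nf)) {
      fr <- coords[m, , , drop = TRUE]
      fit <- kabsch_superpose(fr, ref)
      coords[m, , ] <- sweep(fr, 2, colMeans(fr)) %*% fit$rotation +
        matrix(colMeans(ref), nrow(ref), 3, byrow = TRUE)
    }
    coords
  }
  aligned <- align_to(sel_coords, sel_coords[1, , , drop = TRUE])
  mean_struct <- apply(aligned, c(2, 3), mean)
  aligned <- align_to(aligned, mean_struct)
  mean_struct <- apply(aligned, c(2, 3), mean)
  dev2 <- vapply(seq_len(nf), function(m) {
    rowSums((aligned[m, , , drop = TRUE] - mean_struct)^2)
  }, double(length(selection)))
  vals <- sqrt(rowMeans(matrix(dev2, nrow = length(selection))))
  if (units == "nm") vals <- vals / 10
  tibble::tibble(chain = atoms$chain, resno = atoms$resno,
    resname = atoms$resname, atom = atoms$name, value = vals,
    metric = paste0("rmsf_", units))
}

frame_complex <- function(traj, m) {
  np <- nrow(traj$topology$protein)
  cx <- traj$topology
  xyz <- traj$coords[m, , , drop = TRUE]
  cx$protein$x <- xyz[seq_len(np), 1]
  cx$protein$y <- xyz[seq_len(np), 2]
  cx$protein$z <- xyz[seq_len(np), 3]
  if (nrow(cx$ligand) > 0) {
    li <- np + seq_len(nrow(cx$ligand))
    cx$ligand$x <- xyz[li, 1]; cx$ligand$y <- xyz[li, 2]; cx$ligand$z <- xyz[li, 3]
  }
  cx
}

#' Intermolecular hydrogen-bond count over time
#'
#' Counts ligand-protein polar (N/O) atom pairs within the hydrogen-bond
#' cutoff in every frame, using the same criterion as [find_hbonds()]
#' (distance mode).
#'
#' @param traj A `trajectory` whose topology includes a ligand.
#' @param criteria An [interaction_criteria()] object.
#' @return A tibble with columns `time` (ps), `value` (count), `metric`.
#' @export
hbond_count_series <- function(traj, criteria = interaction_criteria()) {
  if (nrow(traj$topology$ligand) == 0) {
    abort("Trajectory topology has no ligand: cannot count intermolecular H-bonds.")
  }
  np <- nrow(traj$topology$protein)
  lig_idx <- np + which(traj$topology$ligand$is_polar)
  prot_idx <- which(traj$topology$protein$is_polar)
  if (length(lig_idx) == 0 || length(prot_idx) == 0) {
    return(tibble::tibble(time = traj$times, value = 0, metric = "hbond_count"))
  }
  vals <- vapply(seq_len(n_frames(traj)), function(m) {
    xyz <- traj$coords[m, , , drop = TRUE]
    d <- cross_dist(xyz[lig_idx, , drop = FALSE], xyz[prot_idx, , drop = FALSE])
    sum(d <= criteria$hbond_cutoff)
  }, double(1))
  tibble::tibble(time = traj$times, value = vals, metric = "hbond_count")
}

golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Samples points on each atom's probe-expanded sphere (radius
#' `r_vdw + probe`) using a golden-spiral lattice; a point is accessible if
#' it lies outside every neighbouring atom's expanded sphere. Per-atom SASA
#' is the accessible fraction times the expanded-sphere area.
#'
#' @param atoms An atom tibble with `x`, `y`, `z`, `element` (e.g. the
#'   `protein` table of a complex), or a `complex_structure` (protein and
#'   ligand atoms combined).
#' @param probe Probe radius in Angstrom (water: 1.4).
#' @param n_points Sample points per atom sphere.
#' @return A list with `total` (squared Angstrom) and `per_atom` (tibble
#'   with `serial`, `element`, `radius`, `area`).
#' @export
shrake_rupley_sasa <- function(atoms, probe = 1.4, n_points = 960) {
  if (inherits(atoms, "complex_structure")) {
    atoms <- dplyr::bind_rows(atoms$protein, atoms$ligand)
  }
  stopifnot(n_points >= 1, probe >= 0)
  el <- atoms$element
  unknown <- setdiff(unique(el), names(BONDI_RADII))
  if (length(unknown) > 0) {
    abort(paste0("No van der Waals radius for element(s): ",
      paste(unknown, collapse = ", ")))
  }
  rad <- unname(BONDI_RADII[el]) + probe
  xyz <- xyz_mat(atoms)
  n <- nrow(xyz)
  sphere <- golden_spiral_points(n_points)
  areas <- double(n)
  pair_d <- cross_dist(xyz, xyz)
  for (i in seq_len(n)) {
    neigh <- which(pair_d[i, ] < rad[i] + rad & seq_len(n) != i)
    if (length(neigh) == 0) {
      areas[i] <- 4 * pi * rad[i]^2
      next
    }
    pts <- sphere * rad[i]
    pts <- sweep(pts, 2, xyz[i, ], "+")
    buried <- rep(FALSE, n_points)
    for (j in neigh) {
      dx <- pts[, 1] - xyz[j, 1]
      dy <- pts[, 2] - xyz[j, 2]
      dz <- pts[, 3] - xyz[j, 3]
      buried <- buried | (dx * dx + dy * dy + dz * dz < rad[j]^2)
      if (all(buried)) break
    }
    areas[i] <- mean(!buried) * 4 * pi * rad[i]^2
  }
  per_atom <- tibble::tibble(
    serial = if ("serial" %in% names(atoms)) atoms$serial else seq_len(n),
    element = el, radius = rad - probe, area = areas
  )
  list(total = sum(areas), per_atom = per_atom)
}

#' SASA time series over a trajectory
#'
#' Total Shrake-Rupley SASA of the complex for every frame.
#'
#' @param traj A `trajectory`.
#' @inheritParams shrake_rupley_sasa
#' @return A tibble with columns `time` (ps), `value` (squared Angstrom),
#'   `metric`.
#' @export
sasa_series <- function(traj, probe = 1.4, n_points = 240) {
  vals <- vapply(seq_len(n_frames(traj)), function(m) {
    shrake_rupley_sasa(frame_complex(traj, m), probe = probe,
      n_points = n_points)$total
  }, double(1))
  tibble::tibble(time = traj$times, value = vals, metric = "sasa_A2")
}

#' Summarise a metric distribution
#'
#' Order statistics (linear-interpolation quartiles) plus mean and standard
#' deviation, as used for violin-plot style summaries of trajectory
#' metrics.
#'
#' @param series A numeric vector, or a tibble with a `value` column (as
#'   returned by the series functions).
#' @return A one-row tibble with `n`, `min`, `q1`, `median`, `q3`, `max`,
#'   `mean`, `sd`.
#' @export
summarize_distribution <- function(series) {
  v <- if (is.data.frame(series)) series$value else as.numeric(series)
  if (length(v) == 0) abort("Cannot summarise an empty series.")
  q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
  tibble::tibble(
    n = length(v), min = min(v), q1 = q[1], median = q[2], q3 = q[3],
    max = max(v), mean = mean(v), sd = if (length(v) > 1) sd(v) else 0
  )
}
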