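# Seeded synthetic-data generators with exact ground truth for every
# pipeline stage: planted-contact complexes for the interaction profiler,
# Gaussian-jitter trajectories (optionally with an intermittent planted
# hydrogen bond), 4PL dose-response readings, and FRAP calibration
# standards. Every generator is a pure function of (spec, seed).

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# direction respecting per-type constraints and angular separation from
# previously placed plants
draw_direction <- function(type, placed, min_cos = cos(35 * pi / 180)) {
  xhat <- c(1, 0, 0)
  for (i in 1:2000) {
    u <- random_unit()
    ok <- switch(type,
      hbond = TRUE,
      pistack = abs(sum(u * xhat)) <= 0.3,
      hydrophobic = sum(u * xhat) <= 0
    )
    if (!ok) next
    if (length(placed) > 0 &&
      any(vapply(placed, function(w) sum(u * w), double(1)) > min_cos)) {
      next
    }
    return(u)
  }
  abort("Could not place a plant direction: spec too crowded.")
}

perp_unit <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v / sqrt(sum(v^2))
}

plant_atom_row <- function(serial, name, element, resname, chain, resno, pos) {
  tibble::tibble(
    serial = serial, name = name, resname = resname, chain = chain,
    resno = resno, x = pos[1], y = pos[2], z = pos[3], element = element,
    is_polar = element %in% c("N", "O"), is_carbon = element == "C",
    aromatic = FALSE, charge = NA_real_, ad_type = NA_character_
  )
}

build_asn_plant <- function(anchor, u, d, resno, serial0) {
  v <- perp_unit(u)
  pos <- list(
    OD1 = anchor + d * u,
    CG = anchor + (d + 1.25) * u,
    ND2 = anchor + (d + 2.0) * u + 1.0 * v,
    CB = anchor + (d + 2.75) * u,
    CA = anchor + (d + 4.25) * u,
    N = anchor + (d + 5.2) * u + 1.0 * v,
    C = anchor + (d + 5.75) * u,
    O = anchor + (d + 6.9) * u - 0.6 * v
  )
  el <- c(OD1 = "O", CG = "C", ND2 = "N", CB = "C", CA = "C", N = "N",
    C = "C", O = "O")
  purrr::imap_dfr(pos, function(p, nm) {
    plant_atom_row(serial0 + which(names(pos) == nm), nm, el[[nm]],
      "ASN", "A", resno, p)
  })
}

build_phe_plant <- function(anchor, u, d, resno, serial0) {
  v <- perp_unit(u)
  center <- anchor + (d + 1.39) * u
  ring_names <- c("CZ", "CE1", "CD1", "CG", "CD2", "CE2")
  phis <- (seq_along(ring_names) - 1) * 60 * pi / 180
  ring <- purrr::map2(ring_names, phis, function(nm, phi) {
    center + 1.39 * (cos(phi) * (-u) + sin(phi) * v)
  })
  names(ring) <- ring_names
  extra <- list(
    CB = anchor + (d + 2 * 1.39 + 1.5) * u,
    CA = anchor + (d + 2 * 1.39 + 3.0) * u,
    N = anchor + (d + 2 * 1.39 + 3.9) * u + 1.0 * v,
    C = anchor + (d + 2 * 1.39 + 4.5) * u,
    O = anchor + (d + 2 * 1.39 + 5.6) * u - 0.6 * v
  )
  pos <- c(ring, extra)
  el <- setNames(c(rep("C", 6), "C", "C", "N", "C", "O"), names(pos))
  purrr::imap_dfr(pos, function(p, nm) {
    plant_atom_row(serial0 + which(names(pos) == nm), nm, el[[nm]],
      "PHE", "A", resno, p)
  })
}

build_leu_plant <- function(anchor, u, d, resno, serial0) {
  v <- perp_unit(u)
  pos <- list(
    CD1 = anchor + d * u,
    CG = anchor + (d + 1.5) * u,
    CD2 = anchor + (d + 2.4) * u + 1.2 * v,
    CB = anchor + (d + 3.0) * u,
    CA = anchor + (d + 4.5) * u,
    N = anchor + (d + 5.4) * u + 1.0 * v,
    C = anchor + (d + 6.0) * u,
    O = anchor + (d + 7.1) * u - 0.6 * v
  )
  el <- c(CD1 = "C", CG = "C", CD2 = "C", CB = "C", CA = "C", N = "N",
    C = "C", O = "O")
  purrr::imap_dfr(pos, function(p, nm) {
    plant_atom_row(serial0 + which(names(pos) == nm), nm, el[[nm]],
      "LEU", "A", resno, p)
  })
}

build_gly_decoy <- function(resno, serial0) {
  base <- random_unit() * stats::runif(1, 12, 16)
  v <- perp_unit(base / sqrt(sum(base^2)))
  pos <- list(N = base, CA = base + 1.45 * v, C = base + 2.9 * v,
    O = base + 2.9 * v + 1.2 * base / sqrt(sum(base^2)))
  el <- c(N = "N", CA = "C", C = "C", O = "O")
  purrr::imap_dfr(pos, function(p, nm) {
    plant_atom_row(serial0 + which(names(pos) == nm), nm, el[[nm]],
      "GLY", "A", resno, p)
  })
}

# inline brute-force contact scan, independent of the profiler functions
brute_force_residues <- function(protein, ligand, criteria) {
  res_hb <- character(0); res_pi <- character(0); res_hp <- character(0)
  ring <- AROMATIC_RING_ATOMS
  for (i in seq_len(nrow(ligand))) {
    lx <- c(ligand$x[i], ligand$y[i], ligand$z[i])
    for (j in seq_len(nrow(protein))) {
      px <- c(protein$x[j], protein$y[j], protein$z[j])
      dd <- sqrt(sum((lx - px)^2))
      rid <- paste0(protein$resname[j], protein$resno[j])
      if (ligand$is_polar[i] && protein$is_polar[j] && dd <= criteria$hbond_cutoff) {
        res_hb <- union(res_hb, rid)
      }
      if (ligand$is_carbon[i] && protein$is_carbon[j] &&
        protein$resname[j] %in% criteria$hydrophobic_residues &&
        !(protein$name[j] %in% BACKBONE_ATOMS) &&
        dd <= criteria$hydrophobic_cutoff) {
        res_hp <- union(res_hp, rid)
      }
      if (protein$resname[j] %in% criteria$aromatic_residues &&
        protein$resname[j] %in% names(ring) &&
        protein$name[j] %in% ring[[protein$resname[j]]] &&
        dd <= criteria$pistack_cutoff) {
        res_pi <- union(res_pi, rid)
      }
    }
  }
  list(hbond = sort(res_hb), pistack = sort(res_pi), hydrophobic = sort(res_hp))
}

#' Generate a toy complex with planted interactions
#'
#' Builds a three-atom probe ligand (one polar oxygen, one aromatic carbon,
#' one aliphatic carbon) surrounded by synthetic residues positioned so
#' that exactly the requested contacts exist: ASN side-chain oxygens at
#' hydrogen-bond range, PHE aromatic rings at pi-stacking range, LEU
#' side-chain carbons at hydrophobic range, plus optional GLY decoy
#' residues placed at least 2 Angstrom beyond the largest cutoff. The
#' construction is verified by an internal brute-force distance scan and
#' retried with fresh geometry (bounded) if any accidental contact arises.
#'
#' @param n_hbonds,n_pistacks,n_hydrophobic Number of planted residues per
#'   interaction type.
#' @param hbond_distance,pistack_distance,hydrophobic_distance Target
#'   contact distances (Angstrom), scalar or one per plant; each must not
#'   exceed its cutoff.
#' @param n_decoys Number of decoy residues beyond all cutoffs.
#' @param criteria An [interaction_criteria()] object.
#' @param seed Integer seed; identical (spec, seed) reproduce identical
#'   coordinates.
#' @param max_attempts Geometry retries before declaring the requested
#'   plant set infeasible.
#' @return A list with `complex` (a `complex_structure`) and `expected`
#'   (list of sorted residue ids `hbond_residues`, `pistack_residues`,
#'   `hydrophobic_residues`).
#' @export
gen_planted_complex <- function(n_hbonds = 0, n_pistacks = 0,
                                n_hydrophobic = 0,
                                hbond_distance = 3.0,
                                pistack_distance = 5.0,
                                hydrophobic_distance = 3.8,
                                n_decoys = 0,
                                criteria = interaction_criteria(),
                                seed = 1, max_attempts = 25) {
  d_hb <- rep_len(hbond_distance, max(n_hbonds, 1))[seq_len(n_hbonds)]
  d_pi <- rep_len(pistack_distance, max(n_pistacks, 1))[seq_len(n_pistacks)]
  d_hp <- rep_len(hydrophobic_distance, max(n_hydrophobic, 1))[seq_len(n_hydrophobic)]
  if (any(d_hb > criteria$hbond_cutoff) || any(d_pi > criteria$pistack_cutoff) ||
    any(d_hp > criteria$hydrophobic_cutoff)) {
    abort("Planted target distances must not exceed the corresponding cutoffs.")
  }
  ligand <- dplyr::bind_rows(
    plant_atom_row(1L, "O1", "O", "LIG", "L", 1L, c(0, 0, 0)),
    plant_atom_row(2L, "C1", "C", "LIG", "L", 1L, c(1.4, 0, 0)),
    plant_atom_row(3L, "C2", "C", "LIG", "L", 1L, c(-1.4, 0, 0))
  )
  ligand$aromatic[2] <- TRUE
  anchor_o <- c(0, 0, 0); anchor_c <- c(-1.4, 0, 0)

  for (attempt in seq_len(max_attempts)) {
    set.seed(seed + (attempt - 1) * 7919)
    placed <- list()
    protein <- atom_cols(0)
    resno <- 100L; serial0 <- 10L
    expected <- list(hbond = character(0), pistack = character(0),
      hydrophobic = character(0))
    feasible <- TRUE
    add_plant <- function(type, d, builder, anchor) {
      u <- draw_direction(type, placed)
      placed[[length(placed) + 1]] <<- u
      resno <<- resno + 1L
      res <- builder(anchor, u, d, resno, serial0)
      serial0 <<- serial0 + nrow(res) + 1L
      protein <<- dplyr::bind_rows(protein, res)
      expected[[type]] <<- union(expected[[type]], paste0(res$resname[1], resno))
    }
    ok <- tryCatch({
      for (d in d_hb) add_plant("hbond", d, build_asn_plant, anchor_o)
      for (d in d_pi) add_plant("pistack", d, build_phe_plant, anchor_o)
      for (d in d_hp) add_plant("hydrophobic", d, build_leu_plant, anchor_c)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) next
    for (k in seq_len(n_decoys)) {
      resno <- resno + 1L
      dec <- build_gly_decoy(resno, serial0)
      serial0 <- serial0 + nrow(dec) + 1L
      protein <- dplyr::bind_rows(protein, dec)
    }
    found <- brute_force_residues(protein, ligand, criteria)
    if (identical(found$hbond, sort(expected$hbond)) &&
      identical(found$pistack, sort(expected$pistack)) &&
      identical(found$hydrophobic, sort(expected$hydrophobic))) {
      cx <- new_complex(protein, ligand, ligand_name = "PROBE")
      return(list(
        complex = cx,
        expected = list(
          hbond_residues = sort(expected$hbond),
          pistack_residues = sort(expected$pistack),
          hydrophobic_residues = sort(expected$hydrophobic)
        )
      ))
    }
  }
  abort(paste0("Infeasible plant spec: no accidental-contact-free geometry ",
    "found in ", max_attempts, " attempts."))
}

#' Generate a Gaussian-jitter trajectory around a reference complex
#'
#' Frames are the reference coordinates plus iid isotropic Gaussian noise
#' of standard deviation `sigma` per coordinate. Optionally a designated
#' ligand-protein polar atom pair is planted inside the hydrogen-bond
#' cutoff in exactly `round(fraction * n_frames)` frames (chosen by seeded
#' sampling): in planted frames the designated ligand atom sits exactly
#' `bond_distance` from its (jittered) protein partner, and well outside
#' the cutoff otherwise, so the mean hydrogen-bond count is exactly the
#' requested fraction when no other polar pair comes into range.
#'
#' @param reference A `complex_structure` (ligand required when planting).
#' @param sigma Noise standard deviation per coordinate, Angstrom.
#' @param n_frames Number of frames (the campaign's analysis used 5000).
#' @param planted_hbond_fraction Fraction of frames with the planted bond
#'   present, or `NULL` for no plant.
#' @param bond_distance Planted pair distance inside the cutoff.
#' @param dt Frame spacing in ps (100 ns / 5000 frames = 20 ps).
#' @param criteria Criteria supplying the hydrogen-bond cutoff.
#' @param seed Integer seed.
#' @return A `trajectory`.
#' @export
gen_jitter_trajectory <- function(reference, sigma = 0.1, n_frames = 5000,
                                  planted_hbond_fraction = NULL,
                                  bond_distance = 3.0, dt = 20,
                                  criteria = interaction_criteria(),
                                  seed = 1) {
  stopifnot(sigma >= 0, n_frames >= 1)
  set.seed(seed)
  np <- nrow(reference$protein); nl <- nrow(reference$ligand)
  base <- rbind(xyz_mat(reference$protein),
    if (nl > 0) xyz_mat(reference$ligand))
  n_atoms <- np + nl
  coords <- array(rep(base, each = n_frames), dim = c(n_frames, n_atoms, 3))
  if (sigma > 0) {
    coords <- coords + array(stats::rnorm(n_frames * n_atoms * 3, 0, sigma),
      dim = c(n_frames, n_atoms, 3))
  }
  if (!is.null(planted_hbond_fraction)) {
    f <- planted_hbond_fraction
    stopifnot(f >= 0, f <= 1)
    if (nl == 0) abort("Planting an H-bond requires a ligand in the reference.")
    lig_polar <- which(reference$ligand$is_polar)
    prot_polar <- which(reference$protein$is_polar)
    if (length(lig_polar) == 0 || length(prot_polar) == 0) {
      abort("Planting an H-bond requires polar atoms on both sides.")
    }
    li <- np + lig_polar[1]; pj <- prot_polar[1]
    n_on <- round(f * n_frames)
    on_frames <- sort(sample.int(n_frames, n_on))
    u <- c(1, 0, 0)
    off_dist <- criteria$hbond_cutoff + 5
    for (m in seq_len(n_frames)) {
      dd <- if (m %in% on_frames) bond_distance else off_dist
      coords[m, li, ] <- coords[m, pj, ] + dd * u
    }
  }
  new_trajectory(reference, coords, times = (seq_len(n_frames) - 1) * dt)
}

#' Generate triplicate 4PL dose-response data
#'
#' Activities are drawn from the four-parameter logistic curve
#' `y = d + (a - d)/(1 + (x/c)^b)` at the assay's concentration series,
#' with seeded Gaussian noise. The generating parameters are attached as
#' the `truth` attribute.
#'
#' @param a,d Lower/upper asymptotes (% activity).
#' @param c Inflection concentration (micromolar).
#' @param b Hill-type slope.
#' @param noise_sd Gaussian noise SD in % activity.
#' @param n_reps Replicates per concentration.
#' @param concentrations Concentration series (micromolar); default is the
#'   assay's two-fold series 3.125-100.
#' @param compound Compound label.
#' @param seed Integer seed.
#' @return A tibble with columns `compound`, `concentration`, `replicate`,
#'   `activity`; attribute `truth` holds `list(a, d, c, b)`.
#' @export
gen_dose_response <- function(a = 0, d = 100, c = 10, b = 1.3, noise_sd = 0,
                              n_reps = 3,
                              concentrations = c(3.125, 6.25, 12.5, 25, 50, 100),
                              compound = "compound", seed = 1) {
  stopifnot(c > 0, noise_sd >= 0, n_reps >= 1)
  set.seed(seed)
  grid <- tidyr::expand_grid(concentration = concentrations,
    replicate = seq_len(n_reps))
  y <- four_pl_response(grid$concentration, a, b, c, d)
  if (noise_sd > 0) y <- y + stats::rnorm(nrow(grid), 0, noise_sd)
  out <- tibble::tibble(compound = compound,
    concentration = grid$concentration, replicate = grid$replicate,
    activity = y)
  attr(out, "truth") <- list(a = a, d = d, c = c, b = b)
  out
}

#' Generate FRAP Trolox calibration standards
#'
#' (concentration, absorbance) pairs on a stated line plus seeded Gaussian
#' noise, for exercising [frap_trolox_equivalents()] with known truth.
#'
#' @param slope,intercept Calibration line parameters.
#' @param noise_sd Absorbance noise SD.
#' @param n Number of standards (at least 3).
#' @param concentrations Standard concentrations (micromolar Trolox).
#' @param seed Integer seed.
#' @return A tibble with columns `concentration`, `absorbance`; attribute
#'   `truth` holds `list(slope, intercept)`.
#' @export
gen_trolox_standards <- function(slope = 0.002, intercept = 0.05,
                                 noise_sd = 0, n = 6,
                                 concentrations = seq(100, 1000, length.out = n),
                                 seed = 1) {
  if (n < 3) abort("At least 3 standards are required.")
  set.seed(seed)
  ab <- intercept + slope * concentrations
  if (noise_sd > 0) ab <- ab + stats::rnorm(n, 0, noise_sd)
  out <- tibble::tibble(concentration = concentrations, absorbance = ab)
  attr(out, "truth") <- list(slope = slope, intercept = intercept)
  out
}
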