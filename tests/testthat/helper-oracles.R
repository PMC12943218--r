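# Shared fixtures and independent oracles for the test suite.

# minimal atom-row builder for hand-placed test geometries
atom_row <- function(serial, name, element, resname, resno, xyz,
                     chain = "A", aromatic = FALSE) {
  tibble::tibble(
    serial = as.integer(serial), name = name, resname = resname,
    chain = chain, resno = as.integer(resno),
    x = xyz[1], y = xyz[2], z = xyz[3], element = element,
    is_polar = element %in% c("N", "O"), is_carbon = element == "C",
    aromatic = aromatic, charge = NA_real_, ad_type = NA_character_
  )
}

toy_complex <- function(protein_rows, ligand_rows, name = "TOY") {
  new_complex(dplyr::bind_rows(protein_rows), dplyr::bind_rows(ligand_rows),
    ligand_name = name)
}

# Brute-force all-pairs contact oracle, written independently of the
# package's vectorised finders: plain double loops over atoms.
brute_profile <- function(cx, criteria = interaction_criteria()) {
  ring <- list(
    PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
  )
  backbone <- c("N", "CA", "C", "O", "OXT")
  hb <- character(0); pp <- character(0); hp <- character(0)
  n_hb <- 0L; n_pp <- 0L; n_hp <- 0L
  lig <- cx$ligand; prot <- cx$protein
  for (i in seq_len(nrow(lig))) {
    for (j in seq_len(nrow(prot))) {
      d <- sqrt((lig$x[i] - prot$x[j])^2 + (lig$y[i] - prot$y[j])^2 +
        (lig$z[i] - prot$z[j])^2)
      rid <- paste0(prot$resname[j], prot$resno[j])
      if (lig$element[i] %in% c("N", "O") && prot$element[j] %in% c("N", "O") &&
        d <= criteria$hbond_cutoff) {
        hb <- union(hb, rid); n_hb <- n_hb + 1L
      }
      if (lig$element[i] == "C" && prot$element[j] == "C" &&
        prot$resname[j] %in% criteria$hydrophobic_residues &&
        !(prot$name[j] %in% backbone) && d <= criteria$hydrophobic_cutoff) {
        hp <- union(hp, rid); n_hp <- n_hp + 1L
      }
      if (prot$resname[j] %in% criteria$aromatic_residues &&
        !is.null(ring[[prot$resname[j]]]) &&
        prot$name[j] %in% ring[[prot$resname[j]]] &&
        d <= criteria$pistack_cutoff) {
        pp <- union(pp, rid); n_pp <- n_pp + 1L
      }
    }
  }
  list(
    hbond_residues = sort(hb), pistack_residues = sort(pp),
    hydrophobic_residues = sort(hp),
    n_contacts = c(hbond = n_hb, pistack = n_pp, hydrophobic = n_hp)
  )
}

# random complex with realistic residue/atom names, <= 200 atoms
random_complex <- function(seed, n_res = 20, n_lig = 8, box = 14) {
  set.seed(seed)
  resdefs <- list(
    ASN = c(N = "N", CA = "C", C = "C", O = "O", CB = "C", CG = "C",
      OD1 = "O", ND2 = "N"),
    LEU = c(N = "N", CA = "C", C = "C", O = "O", CB = "C", CG = "C",
      CD1 = "C", CD2 = "C"),
    PHE = c(N = "N", CA = "C", C = "C", O = "O", CB = "C", CG = "C",
      CD1 = "C", CD2 = "C", CE1 = "C", CE2 = "C", CZ = "C"),
    SER = c(N = "N", CA = "C", C = "C", O = "O", CB = "C", OG = "O"),
    TYR = c(N = "N", CA = "C", C = "C", O = "O", CB = "C", CG = "C",
      CD1 = "C", CD2 = "C", CE1 = "C", CE2 = "C", CZ = "C", OH = "O"),
    GLY = c(N = "N", CA = "C", C = "C", O = "O")
  )
  serial <- 0L
  prot <- purrr::map_dfr(seq_len(n_res), function(r) {
    rn <- sample(names(resdefs), 1)
    center <- stats::runif(3, -box / 2, box / 2)
    atoms <- resdefs[[rn]]
    purrr::imap_dfr(atoms, function(el, nm) {
      serial <<- serial + 1L
      atom_row(serial, nm, el, rn, r, center + stats::rnorm(3, 0, 1.2))
    })
  })
  lig <- purrr::map_dfr(seq_len(n_lig), function(i) {
    el <- sample(c("C", "C", "O", "N"), 1)
    atom_row(1000L + i, paste0(el, i), el, "LIG", 1L,
      stats::runif(3, -4, 4), chain = "L", aromatic = el == "C" && i %% 2 == 0)
  })
  new_complex(prot, lig, "RND")
}

# apply one rigid rotation + translation to every atom of a complex
transform_complex <- function(cx, rot, trans) {
  tf <- function(tb) {
    xyz <- as.matrix(tb[, c("x", "y", "z")]) %*% rot +
      matrix(trans, nrow(tb), 3, byrow = TRUE)
    tb$x <- xyz[, 1]; tb$y <- xyz[, 2]; tb$z <- xyz[, 3]
    tb
  }
  new_complex(tf(cx$protein), tf(cx$ligand), cx$ligand_name)
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# published reference inputs reused across tests
published_affinities <- function() {
  tibble::tibble(
    compound = c("EGCG", "Chrysin", "Apigenin", "Luteolin", "Naringenin",
      "Myricetin", "Quercetin", "Kaempferol"),
    affinity = c(-9.10, -8.35, -8.04, -8.01, -7.96, -7.84, -7.69, -7.67)
  )
}

vina_pdbqt_text <- function(affinities) {
  unlist(purrr::imap(affinities, function(a, i) {
    c(
      sprintf("MODEL %d", i),
      sprintf("REMARK VINA RESULT:    %6.2f      0.000      0.000", a),
      "ROOT",
      sprintf("ATOM      1  C1  LIG L   1    %8.3f%8.3f%8.3f  0.00  0.00     0.035 C ",
        1.0 + i, 2.0, 3.0),
      sprintf("ATOM      2  O1  LIG L   1    %8.3f%8.3f%8.3f  0.00  0.00    -0.350 OA",
        2.5 + i, 2.0, 3.0),
      "ENDROOT",
      "TORSDOF 1",
      "ENDMDL"
    )
  }))
}
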