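crit <- interaction_criteria()

hbond_pair <- function(d) {
  toy_complex(
    atom_row(1, "N", "N", "ASN", 458, c(0, 0, d)),
    atom_row(100, "O1", "O", "LIG", 1, c(0, 0, 0), chain = "L")
  )
}

test_that("hydrogen-bond cutoff is inclusive at 3.5 Angstrom", {
  expect_equal(nrow(find_hbonds(hbond_pair(3.4), crit)), 1)
  expect_equal(nrow(find_hbonds(hbond_pair(3.5), crit)), 1)
  expect_equal(nrow(find_hbonds(hbond_pair(3.6), crit)), 0)
})

test_that("hydrophobic contacts pair ligand carbons with listed side-chain carbons", {
  mk <- function(resname, atname, element, d) {
    toy_complex(
      atom_row(1, atname, element, resname, 182, c(0, 0, d)),
      atom_row(100, "C1", "C", "LIG", 1, c(0, 0, 0), chain = "L")
    )
  }
  expect_equal(nrow(find_hydrophobic(mk("LEU", "CD1", "C", 3.9), crit)), 1)
  expect_equal(nrow(find_hydrophobic(mk("SER", "OG", "O", 3.9), crit)), 0)
  expect_equal(nrow(find_hydrophobic(mk("SER", "CB", "C", 3.9), crit)), 0)
  expect_equal(nrow(find_hydrophobic(mk("LEU", "CD1", "C", 4.2), crit)), 0)
  # backbone carbons of listed residues do not count
  expect_equal(nrow(find_hydrophobic(mk("LEU", "CA", "C", 3.0), crit)), 0)
})

test_that("pi-stacking proximity uses aromatic ring atoms within 5.5 Angstrom", {
  mk <- function(resname, atname, d, aromatic = TRUE) {
    toy_complex(
      atom_row(1, atname, "C", resname, 435, c(0, 0, d)),
      atom_row(100, "C1", "C", "LIG", 1, c(0, 0, 0), chain = "L",
        aromatic = aromatic)
    )
  }
  expect_equal(nrow(find_pi_stacking(mk("PHE", "CZ", 5.0), crit)), 1)
  expect_equal(nrow(find_pi_stacking(mk("PHE", "CZ", 5.6), crit)), 0)
  expect_equal(nrow(find_pi_stacking(mk("TYR", "CD1", 5.4), crit)), 1)
  # TYR hydroxyl oxygen is not a ring atom
  cx <- toy_complex(
    atom_row(1, "OH", "O", "TYR", 327, c(0, 0, 5.0)),
    atom_row(100, "C1", "C", "LIG", 1, c(0, 0, 0), chain = "L")
  )
  expect_equal(nrow(find_pi_stacking(cx, crit)), 0)
  # literal mode accepts non-aromatic ligand atoms; strict mode does not
  nonarom <- mk("PHE", "CZ", 5.0, aromatic = FALSE)
  expect_equal(nrow(find_pi_stacking(nonarom, crit)), 1)
  expect_equal(nrow(find_pi_stacking(nonarom, crit, strict = TRUE)), 0)
})

test_that("angle mode keeps donors pointing at acceptors and drops others", {
  # ligand hydroxyl donor: O at origin, H on the +z axis toward protein O
  base <- function(hpos) {
    toy_complex(
      atom_row(1, "OD1", "O", "ASN", 458, c(0, 0, 3.0)),
      dplyr::bind_rows(
        atom_row(100, "O1", "O", "LIG", 1, c(0, 0, 0), chain = "L"),
        atom_row(101, "H1", "H", "LIG", 1, hpos, chain = "L")
      )
    )
  }
  toward <- base(c(0, 0, 1.0))    # D-H-A angle = 180
  away <- base(c(0, 0, -1.0))     # D-H-A angle = 0
  expect_equal(nrow(find_hbonds(toward, crit, angle_mode = TRUE)), 1)
  expect_equal(nrow(find_hbonds(away, crit, angle_mode = TRUE)), 0)
  # distance-only default ignores the hydrogen
  expect_equal(nrow(find_hbonds(away, crit)), 1)
  # no hydrogens at all: angle mode falls back to distance
  nohyd <- hbond_pair(3.0)
  expect_equal(nrow(find_hbonds(nohyd, crit, angle_mode = TRUE)), 1)
})

test_that("a residue satisfying two criteria is listed under both types", {
  # PHE ring atom 3.4 A from a polar ligand atom: hbond impossible (C is not
  # polar), but place an extra backbone O to witness an hbond on the same
  # residue that also pi-stacks
  cx <- toy_complex(
    dplyr::bind_rows(
      atom_row(1, "CZ", "C", "PHE", 435, c(0, 0, 5.0)),
      atom_row(2, "O", "O", "PHE", 435, c(0, 3.2, 0))
    ),
    atom_row(100, "O1", "O", "LIG", 1, c(0, 0, 0), chain = "L")
  )
  pr <- profile_complex(cx, crit)
  expect_equal(pr$hbond_residues, "PHE435")
  expect_equal(pr$pistack_residues, "PHE435")
})

test_that("a distant ligand yields an empty profile", {
  cx <- toy_complex(
    atom_row(1, "OD1", "O", "ASN", 458, c(0, 0, 0)),
    atom_row(100, "O1", "O", "LIG", 1, c(100, 0, 0), chain = "L")
  )
  pr <- profile_complex(cx, crit)
  expect_equal(length(pr$hbond_residues), 0)
  expect_equal(length(pr$pistack_residues), 0)
  expect_equal(length(pr$hydrophobic_residues), 0)
  expect_equal(nrow(tidy(pr)), 0)
})

test_that("reference-interaction checks report missing residues", {
  g <- gen_planted_complex(2, 0, 0, seed = 21)
  pr <- profile_complex(g$complex)
  chk <- check_reference_interactions(pr, g$expected$hbond_residues)
  expect_true(chk$pass)
  chk2 <- check_reference_interactions(pr, c(g$expected$hbond_residues, "TRP459"))
  expect_false(chk2$pass)
  expect_equal(chk2$missing, "TRP459")
  expect_true(check_reference_interactions(pr, character(0))$pass)
})

test_that("profiles equal the brute-force all-pairs oracle on random complexes", {
  for (seed in 1:8) {
    cx <- random_complex(seed)
    pr <- profile_complex(cx, crit)
    oracle <- brute_profile(cx, crit)
    expect_setequal(pr$hbond_residues, oracle$hbond_residues)
    expect_setequal(pr$pistack_residues, oracle$pistack_residues)
    expect_setequal(pr$hydrophobic_residues, oracle$hydrophobic_residues)
    expect_equal(sum(pr$contacts$type == "hbond"),
      unname(oracle$n_contacts["hbond"]))
  }
})

test_that("contact sets grow monotonically with the cutoff", {
  for (seed in c(2, 9)) {
    cx <- random_complex(seed)
    for (scale in c(0.6, 0.8, 1.0)) {
      small <- interaction_criteria(
        hbond_cutoff = 3.5 * scale, hydrophobic_cutoff = 4.0 * scale,
        pistack_cutoff = 5.5 * scale
      )
      big <- interaction_criteria(
        hbond_cutoff = 3.5 * scale + 0.7,
        hydrophobic_cutoff = 4.0 * scale + 0.7,
        pistack_cutoff = 5.5 * scale + 0.7
      )
      ps <- profile_complex(cx, small)
      pb <- profile_complex(cx, big)
      expect_true(all(ps$hbond_residues %in% pb$hbond_residues))
      expect_true(all(ps$pistack_residues %in% pb$pistack_residues))
      expect_true(all(ps$hydrophobic_residues %in% pb$hydrophobic_residues))
    }
  }
})

test_that("profiles are invariant under a global rigid transform", {
  cx <- random_complex(4)
  pr0 <- profile_complex(cx, crit)
  for (seed in c(1, 7)) {
    rot <- random_rotation(seed)
    moved <- transform_complex(cx, rot, c(5, -3, 11))
    pr1 <- profile_complex(moved, crit)
    expect_equal(pr1$hbond_residues, pr0$hbond_residues)
    expect_equal(pr1$pistack_residues, pr0$pistack_residues)
    expect_equal(pr1$hydrophobic_residues, pr0$hydrophobic_residues)
    expect_equal(sort(pr1$contacts$distance), sort(pr0$contacts$distance),
      tolerance = 1e-9)
  }
})

test_that("profile residue lists are witnessed, sorted and within cutoff", {
  cx <- random_complex(12)
  pr <- profile_complex(cx, crit)
  cutoffs <- c(hbond = crit$hbond_cutoff, pistack = crit$pistack_cutoff,
    hydrophobic = crit$hydrophobic_cutoff)
  expect_true(all(pr$contacts$distance <= cutoffs[pr$contacts$type]))
  for (ty in names(cutoffs)) {
    listed <- pr[[paste0(ty, "_residues")]]
    witnessed <- unique(pr$contacts$residue[pr$contacts$type == ty])
    expect_setequal(listed, witnessed)
  }
})
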