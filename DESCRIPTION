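Package: flavoscreen
Title: Structure-Based Screening Toolkit for Flavonoid Binders of the GLUT9 Urate Transporter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for a structure-based flavonoid screening
    campaign against the GLUT9 (SLC2A9) urate transporter. Parses docked poses
    (AutoDock Vina PDBQT output) and multi-model PDB complexes, classifies
    protein-ligand contacts (hydrogen bonds, hydrophobic contacts, pi-stacking)
    with distance-based criteria, computes rule-based ADMET verdicts (Lipinski,
    gastrointestinal absorption, blood-brain barrier) from molecular
    descriptors, derives conceptual-DFT global reactivity descriptors from
    frontier-orbital energies via Koopmans' theorem, analyses molecular-dynamics
    trajectories (RMSD, RMSF, hydrogen-bond persistence, Shrake-Rupley SASA),
    and fits four-parameter logistic dose-response curves to antioxidant assay
    data (DPPH, ABTS) with FRAP Trolox-equivalent calibration and ANOVA/Tukey
    comparisons. Includes seeded synthetic-data generators with known ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
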