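# flavoscreen

Post-processing toolkit for structure-based screening of dietary
flavonoids against the GLUT9 (SLC2A9) urate transporter — the renal
transporter whose inhibition lowers serum uric acid, making it a target
for hyperuricemia and gout. The package covers every computational stage
downstream of docking, simulation and the plate reader, for researchers
who need those stages reproducible and testable:

* **Pose handling** — AutoDock-Vina-style PDBQT parsing
  (`read_pdbqt_poses()`), best-pose selection by lowest binding affinity,
  multi-model PDB complexes and trajectories (`read_pdb()`).
* **Interaction profiling** — a distance-based contact classifier
  (`profile_complex()`): hydrogen bonds between ligand and protein N/O
  atoms within 3.5 Å, hydrophobic carbon–carbon contacts to
  PHE/TRP/TYR/LEU/ILE/VAL/ALA/MET/PRO side chains within 4.0 Å, and
  π-stacking proximity to PHE/TRP/TYR ring atoms within 5.5 Å.
* **Rule-based ADMET** — descriptors (MW, Wildman–Crippen LogP, HBD,
  HBA = N+O, Ertl TPSA, rotatable bonds) and verdicts: Lipinski
  violations (MW > 500, LogP > 5, HBD > 5, HBA > 10), GI absorption
  (High iff TPSA ≤ 140 Å²), BBB permeation (Yes iff TPSA ≤ 90 Å² and
  MW ≤ 450).
* **Reactivity descriptors** — Koopmans-theorem conceptual DFT from
  frontier-orbital energies: I = −E(HOMO), A = −E(LUMO), χ = (I+A)/2,
  η = (I−A)/2, S = 1/(2η), ω = χ²/(2η), ΔE = E(LUMO) − E(HOMO).
* **MD metrics** — Kabsch superposition, backbone RMSD vs. frame 1,
  per-residue (Cα) RMSF, intermolecular H-bond counts over time,
  Shrake–Rupley SASA (golden-spiral sampling, Bondi radii, 1.4 Å probe),
  violin-style distribution summaries.
* **Assay analysis** — percent radical scavenging
  100·(A_ctrl − A_sample)/A_ctrl, four-parameter logistic fits
  y = d + (a−d)/(1+(x/c)^b) with analytic IC50
  x = c·((a−d)/(50−d) − 1)^(1/b), FRAP Trolox-equivalent calibration,
  one-way ANOVA + Tukey HSD.
* **Synthetic data** — seeded generators with exact ground truth for all
  of the above (planted-contact complexes, Gaussian-jitter trajectories
  with plantable intermittent H-bonds, 4PL dose–response readings,
  Trolox standards), standing in for the study's un-deposited poses,
  trajectories and absorbances.

The eight-compound screening panel (apigenin, chrysin, quercetin,
kaempferol, luteolin, myricetin, naringenin, EGCG) is embedded with
PubChem CIDs, canonical SMILES, formulas and published reference values
(`flavonoid_compounds()`, `flavonoid_reference_properties()`,
`flavonoid_orbital_energies()`) — no network access required.

## Worked example

```r
library(flavoscreen)

# Reactivity table from the packaged frontier-orbital energies
build_reactivity_table(flavonoid_orbital_energies())
#> # A tibble: 11 × 5
#>    parameter                      unit         EGCG  Chrysin Apigenin
#>  5 HOMO-LUMO Gap (dE)             eV          4.54     4.49     4.45
#>  8 Electronegativity (chi)        eV          3.18     3.68     3.50
#>  9 Chemical Hardness (eta)        eV          2.27     2.24     2.22
#> 10 Chemical Softness (S)          1/eV        0.220    0.223    0.225
#> 11 Electrophilicity Index (omega) eV          2.23     3.02     2.75
#> # ... (total energy, dipole, E(HOMO), E(LUMO), I, A rows elided)

# A planted toy complex recovered by the profiler
g <- gen_planted_complex(n_hbonds = 2, n_pistacks = 1, seed = 7)
profile_complex(g$complex)
#> <interaction_profile> PROBE
#>   H-bond residues:      ASN101, ASN102
#>   pi-stacking residues: PHE103
#>   hydrophobic contacts: -

# Four-parameter logistic fit of synthetic triplicate dose-response data
dr <- gen_dose_response(c = 3.3, b = 1.2, noise_sd = 2,
                        compound = "EGCG", seed = 1)
fit_four_pl(dr)
#> <four_pl_fit> EGCG
#>   a = -9.695, b = 1.241, c = 2.897 uM, d = 99.534
#>   IC50 = 3.367 uM +/- 0.124, r^2 = 0.9910 (n = 18)
```

The reactivity table rows are the global reactivity descriptors derived
from each compound's HOMO/LUMO energies; the higher HOMO and lower
electrophilicity of EGCG track its stronger electron-donating
(antioxidant) character. The profiler output lists, per interaction
type, the residues the generator planted — here two hydrogen-bonding
asparagines and one π-stacking phenylalanine, with the planted truth
recovered exactly. The 4PL fit reports the fitted asymptotes, slope and
inflection, the IC50 read off the fitted curve at 50% activity (± the
SD over per-replicate refits), and r² on the pooled points — here the
estimate brackets the generating inflection of 3.3 µM at 2% noise.

Report bundles mirroring the campaign's summary tables (affinity
ranking, per-compound interaction lists, ADMET, reactivity, IC50/FRAP
with ANOVA annex) come from `run_screening_report()` and
`run_assay_report()`.

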