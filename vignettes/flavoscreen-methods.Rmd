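---
title: "Methods: contact classification, rule-based ADMET, reactivity descriptors, trajectory metrics and dose-response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavoscreen)
```

`flavoscreen` re-implements, as tested and reusable functions, the
computational stages of a structure-based screen of eight dietary
flavonoids against the GLUT9 (SLC2A9) urate transporter: docking-pose
post-processing, a distance-based protein–ligand interaction profiler,
a rule-based ADMET engine, conceptual-DFT reactivity descriptors,
molecular-dynamics trajectory metrics, and antioxidant dose–response
analysis. The original docked poses, trajectories and raw plate-reader
absorbances were not deposited, so the package ships seeded synthetic-data
generators that produce inputs with *known ground truth* for every stage;
those generators are first-class, tested code and define the regression
surface of the package.

This vignette records the models, the tunable parameters, and the design
choices that were genuinely open.

## Docked-pose handling

AutoDock-Vina-style PDBQT output is parsed by `read_pdbqt_poses()`: one
pose per `MODEL` block, the binding affinity (kcal/mol) taken from the
first numeric field of the `REMARK VINA RESULT:` line, rank equal to order
of appearance. Partial charges and AutoDock atom types are parsed and kept
(lossless), but the profiler does not use them. `select_best_pose()`
returns the pose with the lowest (most negative) affinity, ties broken by
rank — the selection rule of the screening protocol, which generated 10
poses per ligand in a 22 x 22 x 22 A box at exhaustiveness 32.

PDB input uses fixed-column (wwPDB) parsing. Policy decisions:

* alternate locations: only altLoc `' '` or `'A'` are kept;
* ligand detection: `HETATM` records whose residue name is not one of the
  twenty standard amino acids; waters are dropped entirely (the receptor
  was prepared with waters and heteroatoms removed);
* multi-`MODEL` files become trajectories (topology = first frame);
* coordinates are Angstrom throughout — no unit conversion at boundaries;
  a `units = "nm"` flag exists only at the metric-output layer.

Malformed coordinate fields fail with the offending line number rather
than silently dropping atoms.

## The interaction profiler

The contact classifier assigns three geometric interaction classes
between a docked ligand and the receptor, with inclusive distance cutoffs
(all tunable through `interaction_criteria()`):

| class | pair | cutoff (default) |
|---|---|---|
| hydrogen bond | ligand N/O — protein N/O | 3.5 A |
| hydrophobic | ligand C — side-chain C of PHE, TRP, TYR, LEU, ILE, VAL, ALA, MET, PRO | 4.0 A |
| pi-stacking | ligand atom — aromatic ring atom of PHE, TRP, TYR | 5.5 A |

Choices that the protocol text leaves open, and how they were resolved:

* **Inclusive cutoffs.** "Within *x* A" is read as `<=`; the boundary
  behaviour is pinned by tests at exactly 3.5 / 4.0 / 5.5 A.
* **Two hydrogen-bond modes.** The default is distance-only, matching the
  screening script's stated criterion. An *angle mode* additionally
  requires a donor–H–acceptor angle of at least 120 degrees whenever a
  covalently bonded hydrogen (within 1.25 A) is present on either
  partner — the classical visualisation-tool criterion. Docked poses may
  or may not carry polar hydrogens, so angle mode falls back to the
  distance rule for pairs with no hydrogens rather than silently dropping
  them. The two modes are kept separate instead of merged.
* **Hydrophobic contacts are carbon–carbon.** Pairing ligand carbons with
  polar side-chain atoms of an apolar residue would be a category error,
  so only side-chain carbons count (backbone C/CA excluded). Whether the
  original analysis measured to all residue atoms cannot be recovered
  from the published residue lists; the restriction is therefore a
  documented package choice.
* **Pi-stacking is proximity-only.** The default (literal) mode lets any
  ligand atom trigger a ring contact; a strict mode requires the ligand
  atom to be flagged aromatic. No ring-plane angle test is applied in
  either mode, because the protocol defines none. Ring atoms are fixed
  name lists (PHE/TYR: CG, CD1, CD2, CE1, CE2, CZ — the TYR hydroxyl
  oxygen is excluded; TRP: the full indole, including NE1).
* Residues are reported once per type as `NAME<number>` (e.g. `ASN458`),
  sorted by chain and residue number.

`profile_complex()` aggregates the three finders;
`check_reference_interactions()` verifies anchor residues (for the
screen's receptor: the co-crystallised ligand's `ASN458`/`TRP459`
hydrogen bonds) against a profile. Correctness is established three ways:
equality with a brute-force all-pairs distance scan on random complexes,
exact recovery of planted ground truth over 50 seeded generator runs, and
invariance under rigid motions plus monotonicity in the cutoffs.

## Rule-based ADMET

`compute_descriptors()` produces the six-descriptor set per molecule:

* molecular weight as the IUPAC-standard-atomic-weight sum over the
  molecular formula (exact; rounding only at presentation);
* LogP (Wildman–Crippen atomic contributions) and TPSA (Ertl fragment
  contributions) from Open Babel via ChemmineOB — the established
  implementations of the published descriptor definitions;
* HBD as the O–H/N–H group count; HBA as the nitrogen + oxygen atom
  count, which is the original rule-of-five definition and reproduces the
  published counts (e.g. 11 for EGCG = its 11 oxygens);
* rotatable bonds by the common "non-ring single bond between two
  non-terminal heavy atoms" SMARTS. Definitions vary across toolkits:
  this yields 1 for the seven single-linker flavonoids (matching the
  published table) but 4 for EGCG where 3 was printed; the EGCG count is
  deliberately not asserted anywhere.

The rule engine (`admet_verdicts()`):

* Lipinski violations: strict inequalities MW > 500, LogP > 5, HBD > 5,
  HBA > 10. The reported label is `"Yes"` only at *zero* violations,
  because the published verdict column labels the one-violation compound
  "No (1)" even though the classic rule tolerates one violation; the raw
  count is kept alongside so either convention is recoverable.
* GI absorption: `High` iff TPSA <= 140 A^2 (boundary inclusive).
* BBB permeation: `Yes` iff TPSA <= 90 A^2 and MW <= 450 g/mol (both
  inclusive).

The eight panel compounds are embedded (`flavonoid_compounds()`: name,
PubChem CID, canonical SMILES, formula, published docking affinity), so
no network access is ever needed.

## Koopmans reactivity descriptors

From frontier-orbital energies in eV (`koopmans_descriptors()`):

I = −E(HOMO), A = −E(LUMO), chi = (I + A)/2, eta = (I − A)/2,
S = 1/(2 eta), omega = chi^2/(2 eta), gap = E(LUMO) − E(HOMO) = 2 eta.

A degenerate gap (eta = 0) raises an explicit error, since softness and
electrophilicity are undefined; an inverted orbital pair warns. Inputs
are eV; a Hartree bridge is explicit (`hartree_to_ev()`, CODATA constant
27.211386 — the source table mixes Hartree for total energies with eV
for orbitals, and silent unit mixing is the classic failure mode here).
Values are exact; `build_reactivity_table()` rounds to 4 decimals at
presentation only. Full quantum-chemistry log parsing is out of scope:
orbital energies enter through a documented CSV layout
(`read_orbitals_csv()`), because log formats drift across program
versions.

The algebraic identities (gap = 2 eta, S·2 eta = 1, omega·2 eta = chi^2,
chi ± eta = I/A) are property-tested on random inputs to machine
precision, and the embedded published orbital energies reproduce all
derived rows to 1e-4.

## Trajectory metrics

* **Superposition** is Kabsch via SVD, constrained to a proper rotation;
  collinear point sets are rejected (the rotation is not unique).
  Cross-checked against numeric minimisation over Euler angles and
  against an independent fitter.
* **RMSD** is computed per frame against *frame 1* after superposition.
  The protocol does not name the reference; the first frame is chosen
  because the published RMSD traces start near zero.
* **RMSF** uses one atom per residue (C-alpha — the published profile is
  "per residue index" without an atom choice) about the mean structure:
  frames are aligned to frame 1, the mean is formed, and frames are
  re-aligned to the mean in one pass. The single pass leaves a
  sub-1e-4 A frame-order dependence, which is accepted.
* **Hydrogen-bond persistence** counts ligand–protein polar pairs within
  the hydrogen-bond cutoff per frame, by the same criterion as the
  profiler's distance mode (module consistency is tested frame-wise).
* **SASA** is Shrake–Rupley with a golden-spiral point lattice
  (default 960 points/atom), Bondi van der Waals radii, and a 1.4 A water
  probe (the protocol states neither radii set nor probe; these are the
  field's defaults). Convergence: 960 points are within 1% of a
  10000-point evaluation on a 20-atom cluster, and a single sphere is
  within 1% of the analytic 4 pi (r + probe)^2.
* `summarize_distribution()` provides the violin-plot order statistics
  (linear-interpolation quartiles).

## Antioxidant assay analysis

Percent scavenging activity is
`100 (A_control − A_sample)/A_control`.

Dose–response curves use the four-parameter logistic model

y = d + (a − d) / (1 + (x/c)^b)

fitted by Levenberg–Marquardt least squares (`minpack.lm`) on pooled
replicate points at the assay's concentration series (3.125, 6.25, 12.5,
25, 50, 100 uM; triplicate). Self-starting values come from the data
range and a log-linear fit to the mid-segment; the fit restarts from five
deterministic initialisations with |b| in [0.1, 20] and c constrained to
the observed concentration range widened 100-fold either side. Flat data
(activity range < 1%) are rejected as degenerate rather than fitted.

The IC50 is defined as the 50%-activity crossing of the *fitted curve*,
solved analytically: x = c ((a − d)/(50 − d) − 1)^(1/b); with asymptotes
0/100 this coincides with the inflection c. The crossing must lie
strictly between the asymptotes, otherwise an explicit no-crossing error
is raised. `ic50_sd` comes from per-replicate refits (matching the
"mean ± SD over triplicates" reporting convention); whether the original
SDs came from refits or the fit covariance is not stated, and refits were
adopted as the more assumption-free choice.

FRAP results are Trolox equivalents from an ordinary least-squares
calibration line; the grams-per-reaction `mass_factor` is an explicit
argument because the per-gram conversion depends on an unstated
mass/dilution scheme. Group comparisons use one-way ANOVA with Tukey HSD
(base `stats::aov`/`TukeyHSD`), flagged at p < 0.05 and p < 0.001.

Calibration is verified by simulation: noiseless 4PL round-trips recover
parameters to 1e-6 relative; at 2%-activity Gaussian noise the median
relative IC50 error over 200 seeded datasets stays below 5%; the ANOVA
type-I error rate over 2000 null simulations is 0.05 ± 0.02.

## The synthetic-data generators

Because no study data were deposited, every stage is exercised against
generated inputs whose truth is known by construction:

* `gen_planted_complex()` builds a three-atom probe ligand (polar O,
  aromatic C, aliphatic C) and places synthetic residues so that exactly
  the requested contacts exist: ASN side-chain oxygens at hydrogen-bond
  range, PHE rings at pi-stacking range, LEU side-chain carbons at
  hydrophobic range, GLY decoys at least 2 A beyond the largest cutoff.
  Residue types are chosen so each plant can trigger only its own
  interaction class; plant directions are angularly separated, and an
  internal brute-force scan verifies the absence of accidental contacts
  (with bounded retries, then an infeasibility error).
* `gen_jitter_trajectory()` adds iid isotropic Gaussian noise to a
  reference (default 5000 frames, 20 ps spacing — the analysis stride of
  a 100 ns run) and can plant an intermittent hydrogen bond present in
  exactly `round(f * n_frames)` frames; the designated pair's distance is
  set deterministically so the mean count is exact.
* `gen_dose_response()` and `gen_trolox_standards()` draw from the stated
  4PL curve / calibration line with seeded Gaussian noise and attach the
  generating truth as an attribute.

All generators are pure functions of (specification, seed): reruns are
bit-identical. What the generators *do not* emulate: correlated
(non-isotropic) protein motion, chemically realistic residue geometry
beyond atom naming, heteroscedastic plate-reader noise, and docking-score
physics. Passing tests therefore demonstrate the correctness of the
*analysis* code under controlled conditions, not the behaviour of the
upstream simulation or assay instruments on real systems.

Noise defaults mirror the study conditions where stated (six
concentrations, triplicates, 5000 frames); where no value is printed, a
single realistic choice was fixed: 2% activity noise (consistent with
the published IC50 SDs of roughly 5–7% of the mean), 0.1 A jitter for
trajectory tests, and Gaussian noise throughout (the published SDs are
the only dispersion information available).

## Problem sizes and numerical notes

The test suite runs at desk scale: random complexes are kept under 200
atoms (where brute force is exact and fast), RMSF calibration uses 50
atoms x 5000 frames, SASA convergence uses a 20-atom cluster, and the
statistical calibrations use 200 dose-response datasets and 2000 ANOVA
null simulations — sizes at which every check is exact or the Monte-Carlo
error is well below the asserted tolerance.

Other numerical choices: distances are computed from squared-norm
expansions clipped at zero; the Kabsch determinant correction guarantees
proper rotations; quartiles are type-7 (linear interpolation); rounding
happens only at presentation layers (2 decimals for masses, 4 for
reactivity tables).

## Known limitations

* The profiler detects no salt bridges, halogen bonds or cation-pi
  contacts, and does not score interaction strength.
* Angle-mode hydrogen bonding requires hydrogens in the input; poses
  without polar hydrogens silently get the distance-only behaviour.
* Absolute RMSD/SASA magnitudes of the original trajectories are not
  reproducible (the trajectories are not public); only the metric
  machinery is validated, against analytic and statistical ground truth.
* Published IC50s cannot be re-derived without the raw absorbances;
  assay validation is via synthetic recovery.
* XTC/TRR trajectory ingestion is not implemented; multi-model PDB is
  the native trajectory format.
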