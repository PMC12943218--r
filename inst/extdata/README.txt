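Small plain-text example inputs.

orbital_energies.csv
  Frontier-orbital energies (B3LYP/6-31G(d), eV) for the three
  DFT-characterised flavonoids, in the key-value CSV layout consumed by
  read_orbitals_csv().

egcg_poses_synthetic.pdbqt
  SYNTHETIC AutoDock-Vina-style multi-pose output (three poses of a toy
  two-atom ligand) for exercising read_pdbqt_poses(); the top affinity
  mirrors the published EGCG docking score. Not a real docking result.
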