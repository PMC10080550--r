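{
  "kind": "ms",
  "description": "ESI-MS titration of the 19-residue SilE fragment SP3 (residues 107-125) at 100 uM with Ag+:peptide ratios 0, 0.5, 1, 2; sequential two-site binding with stepwise KD1 = 0.2 uM and KD2 = 24.5 uM; apo peptide partly detected as a nonspecific gas-phase dimer.",
  "sequence": "AMNEHERAAVAHEFMNNGQ",
  "numbering_offset": 107,
  "kd1": 0.2,
  "kd2": 24.5,
  "p_total": 100.0,
  "ratios": [0.0, 0.5, 1.0, 2.0],
  "z_range": [2, 3],
  "dimer_fraction": 0.3,
  "noise_cv": 0.0,
  "seed": 1722
}
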