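{
  "kind": "nmr",
  "description": "Phenomenological TOCSY titration of the 16-residue SilE fragment SP2 (residues 77-92) with a direction change after 0.5 Ag+ equivalents at the binding-motif residues.",
  "sequence": "ADAHQKMVESHQRMMG",
  "numbering_offset": 77,
  "spectrum_type": "TOCSY",
  "mode": "phenomenological",
  "ratios": [0.0, 0.1, 0.5, 3.0, 10.0],
  "break_ratio": 0.5,
  "noise_sd": 0.0,
  "seed": 1722,
  "site_shifts": [
    {"residue_index": 1,  "d1_f1": 0.010, "d1_f2": 0.006,  "d2_f1": 0.0,   "d2_f2": 0.0},
    {"residue_index": 2,  "d1_f1": 0.010, "d1_f2": 0.006,  "d2_f1": 0.0,   "d2_f2": 0.0},
    {"residue_index": 3,  "d1_f1": 0.010, "d1_f2": 0.006,  "d2_f1": 0.0,   "d2_f2": 0.0},
    {"residue_index": 4,  "d1_f1": 0.038, "d1_f2": -0.026, "d2_f1": 0.028, "d2_f2": 0.033},
    {"residue_index": 5,  "d1_f1": 0.010, "d1_f2": 0.006,  "d2_f1": 0.0,   "d2_f2": 0.0},
    {"residue_index": 6,  "d1_f1": 0.010, "d1_f2": 0.006,  "d2_f1": 0.0,   "d2_f2": 0.0},
    {"residue_index": 7,  "d1_f1": 0.045, "d1_f2": -0.030, "d2_f1": 0.034, "d2_f2": 0.038},
    {"residue_index": 8,  "d1_f1": 0.050, "d1_f2": -0.035, "d2_f1": 0.030, "d2_f2": 0.042},
    {"residue_index": 9,  "d1_f1": 0.010, "d1_f2": 0.006,  "d2_f1": 0.0,   "d2_f2": 0.0},
    {"residue_index": 10, "d1_f1": 0.010, "d1_f2": 0.006,  "d2_f1": 0.0,   "d2_f2": 0.0},
    {"residue_index": 11, "d1_f1": 0.042, "d1_f2": -0.027, "d2_f1": 0.030, "d2_f2": 0.036},
    {"residue_index": 12, "d1_f1": 0.010, "d1_f2": 0.006,  "d2_f1": 0.0,   "d2_f2": 0.0},
    {"residue_index": 13, "d1_f1": 0.010, "d1_f2": 0.006,  "d2_f1": 0.0,   "d2_f2": 0.0},
    {"residue_index": 14, "d1_f1": 0.055, "d1_f2": -0.036, "d2_f1": 0.040, "d2_f2": 0.045},
    {"residue_index": 15, "d1_f1": 0.050, "d1_f2": -0.033, "d2_f1": 0.036, "d2_f2": 0.041},
    {"residue_index": 16, "d1_f1": 0.010, "d1_f2": 0.006,  "d2_f1": 0.0,   "d2_f2": 0.0}
  ]
}
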