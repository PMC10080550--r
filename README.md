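# silbind

Silver-peptide binding analysis from 2D NMR and ESI-MS titrations.

Bacterial silver resistance is mediated in part by SilE, a periplasmic
protein that sequesters Ag⁺ through histidine/methionine (HXXM-type)
motifs. `silbind` implements the complete analysis pipeline for
characterising Ag⁺ binding to SilE-derived model peptides (the 16-residue
fragment SP2, residues 77–92, and the 19-residue fragment SP3, residues
107–125):

- **Chemical shift perturbation (CSP) mapping.** For a homonuclear TOCSY
  cross-peak, CSP = √(Δδ²_H(F1) + Δδ²_H(F2)); for a ¹H-¹³C HSQC cross-peak
  the carbon axis is scaled, CSP = √(Δδ²_H + α·Δδ²_C) with α = 0.3. Signals
  are grouped (Cα/Hα, Cβ/Hβ, Cγ/Hγ, CH₃; TOCSY: NH/Hα vs other) and
  classified as weak (< μ), medium ([μ, μ+σ)) or strong (≥ μ+σ) movers
  from the group mean μ and population σ.
- **Secondary ¹³Cα shifts.** δ_obs(¹³Cα) − δ_rc against a packaged,
  user-replaceable random-coil table; positive deltas indicate helix. An
  ideal helical-wheel helper (100°/residue) tests whether residues share a
  helix face (i+3, i+4 registers).
- **Titration trajectories.** In fast exchange a single binding mode moves
  a cross-peak along a straight line; a second mode bends the path. The
  detector merges sub-noise steps (< 0.005 ppm) and reports a break when
  successive displacement vectors (in the α-weighted plane) turn by ≥ 30°,
  returning the vertex ratio.
- **Sequential two-site equilibrium.** P + Ag ⇌ PAg (K_D1 = [P][Ag]/[PAg])
  and PAg + Ag ⇌ PAg₂ (K_D2 = [PAg][Ag]/[PAg₂]); species concentrations are
  solved by a bracketed root find on free Ag⁺ with both conservation laws
  enforced to 1e-9 relative.
- **ESI-MS adduct analysis.** Theoretical m/z = (k·M + n·m(Ag⁺) +
  (z−n)·m(H⁺))/z for a k-mer with n bound silver ions at charge z;
  centroids are matched within a ppm tolerance across charge states,
  converted to mole fractions (dimers contribute two peptide equivalents to
  the apo pool), and K_D1/K_D2 are fit by deterministic least squares on
  the fractions.
- **Synthetic data.** Generators for fast-exchange NMR titrations
  (equilibrium or phenomenological two-mode paths) and stick ESI-MS
  titrations with known ground truth, including packaged presets
  `"sp2-paper"` and `"sp3-paper"` encoding the experimental designs above.

## Worked example

```r
library(silbind)

peptide_mass("ADAHQKMVESHQRMMG")    # SP2: 1856.123 Da (average)
peptide_mass("AMNEHERAAVAHEFMNNGQ") # SP3: 2156.335 Da

## ESI-MS titration: generate -> assign -> quantify -> fit
cfg   <- sim_preset("sp3-paper")          # 100 uM SP3, ratios 0, 0.5, 1, 2
specs <- generate_ms_titration(cfg)
quants <- lapply(specs, function(s) quantify(assign_species(s, cfg$sequence)))
quants[["ratio_1"]]
#> <titration_quant> f0 0.087, f1 0.846, f2 0.067 (Ag+ 100 / peptide 100 uM)
fit_kds(unname(quants))
#> <fit_result> KD1 = 0.2 uM, KD2 = 24.5 uM (SSE 1.102e-29, converged)

## NMR titration: trajectory direction change
ncfg <- sim_preset("sp2-paper")           # TOCSY ratios 0, 0.1, 0.5, 3, 10
ser  <- generate_nmr_series(ncfg)
tr   <- extract_trajectory(ser, 8L, "H", "HG")  # 84Val NH/Hgamma
detect_direction_change(tr)
#> <breakpoint_result> direction change after ratio 0.5 (max turn 89.5 deg)
```

The fitted constants recover the preset's ground truth exactly on
noiseless data (K_D1 = 0.2 μM, the high-affinity site; K_D2 = 24.5 μM, the
low-affinity site), and the 84Val NH/Hγ cross-peak — like every two-mode
trajectory in the preset — runs straight up to 0.5 Ag⁺ equivalents and
then changes direction, the signature of a second binding mode.

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch with the installed
package, the pipeline's headline quantities: the two average peptide
masses, the two dissociation constants recovered by the full ESI-MS
pipeline from the `sp3-paper` synthetic titration, the breakpoint ratio on
the `sp2-paper` synthetic NMR series, and the maximum silver count
assigned on a full synthetic adduct spectrum. Run it as

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

which writes one JSON object with a numeric `value` (and problem size
`n`) per quantity.
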