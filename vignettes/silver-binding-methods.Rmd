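---
title: "Methods: mapping Ag+ binding to SilE model peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping Ag+ binding to SilE model peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silbind)
```

## The problem

SilE is a periplasmic silver-binding protein implicated in bacterial
Ag⁺ resistance. Its binding capability is carried by His/Met (HXXM-type)
motifs. `silbind` analyses titration experiments on two SilE model
peptides — SP2 (`ADAHQKMVESHQRMMG`, residues 77–92) and SP3
(`AMNEHERAAVAHEFMNNGQ`, residues 107–125) — to answer three questions:
*which residues* engage the metal (CSP mapping), *how many binding modes*
there are (trajectory analysis), and *how strong* the two sites are
(ESI-MS titration fitting).

## Chemical shift perturbation

Both CSP metrics reduce a cross-peak displacement between a reference
spectrum (default ratio 0.0) and an endpoint spectrum (default 10.0) to
one non-negative ppm value:

- TOCSY (¹H/¹H): the plain Euclidean distance on the two proton axes.
- ¹H-¹³C HSQC: `sqrt(d_H^2 + alpha * d_C^2)`. The carbon axis spans tens
  of ppm against the proton axis's few, so its squared displacement is
  scaled by `alpha`; the conventional literature value 0.3 is the default
  and is configurable in `csp_config()`.

Cross-peaks absent at either endpoint are never dropped silently: they
carry `csp = NA` and `mover_class = "missing"` through the whole table.

**Grouping.** HSQC signals are compared only within chemically comparable
groups: Cα/Hα, Cβ/Hβ, Cγ/Hγ and methyl (CH₃) cross-peaks. The methyl set
is an explicit residue/carbon list (Ala Cβ, Val Cγ1/Cγ2, Thr Cγ2, Leu
Cδ1/Cδ2, Ile Cγ2/Cδ1, Met Cε); rarer non-methyl carbons beyond γ —
histidine ring Cδ/Cε in these peptides — are folded into the Cγ/Hγ group
rather than given a fifth group. TOCSY signals are split into backbone
NH/Hα versus all other cross-peaks. These TOCSY and ring-carbon
conventions are this package's documented choices: the source experiments
plotted four HSQC groups, and no finer rule is published.

**Mover classification.** Within each group, with mean μ and standard
deviation σ of the non-missing CSPs: weak < μ ≤ medium < μ+σ ≤ strong.
The bounds are closed on the left so ties break deterministically (CSP
exactly μ is medium, exactly μ+σ is strong); when σ = 0 every record sits
at μ and is classified medium. σ is the population standard deviation by
default (`sigma = "sample"` switches to n−1) — the underlying experiments
do not state which was used, and with group sizes near 10–16 the
difference rarely moves a classification.

## Secondary ¹³Cα shifts and the helical wheel

`secondary_shifts()` subtracts tabulated random-coil ¹³Cα values from the
observed Cα shifts at one titration point; positive deltas indicate
helical tendency, and comparing the apo and endpoint spectra shows
whether metal binding stabilises the helix. The packaged table contains
the standard literature random-coil values; because published tables
differ by a few tenths of a ppm depending on vintage and referencing, the
table is a user-replaceable TSV. No neighbour-sequence corrections are
applied, matching the simple differencing the analysis needs.

`same_helix_face()` formalises the i+3/i+4 register argument with the
ideal helical wheel (100° per residue): two residues are "same face" when
their wheel separation, folded into [0°, 180°], is within a tolerance of
0°. The default tolerance of 80° is chosen so that i+3 (60°) and i+4
(40°) qualify while i+2 (160°) does not. One consequence worth knowing:
directly adjacent residues (i+1, 100°) are *not* same-face under this
rule, so in the SP2 motif set {80His, 83Met, 87His, 90Met, 91Met} every
pair qualifies except the adjacent 90Met/91Met pair — the two methionines
reach one face by the i+3/i+4 relation to 87His rather than to each
other. (An i+7 pair, 20°, and the i+10 pair at exactly 80° also qualify
under the closed bound.)

## Trajectory direction changes

Under fast exchange the observed peak is the population-weighted average
of the free and bound positions, so one binding mode drags a cross-peak
along a straight line as its site saturates, while a second mode with a
different bound-state shift bends the path. The detector makes the visual
criterion explicit:

1. Coordinates are weighted so geometry matches the CSP metric: the HSQC
   carbon axis is multiplied by `sqrt(alpha)`; TOCSY axes are unweighted.
2. Displacement steps shorter than `min_step_ppm` (default 0.005 ppm,
   about twice a typical peak-picking uncertainty) are merged into the
   following step, so jitter cannot fabricate a turn; trailing
   sub-threshold motion folds into the last real step.
3. A break is declared when the angle between successive merged steps
   reaches `turn_threshold_deg` (default 30°, comfortably above the
   few-degree wobble noise produces and below any chemically meaningful
   mode change). The reported `break_ratio` is the vertex point's ratio —
   the last titration point before the new direction.

Both thresholds are configurable because the underlying criterion is a
formalisation of a visual judgement, not a published rule. Turning angles
are invariant under rotation and uniform scaling of the spectrum and a
trajectory of all-sub-threshold motion reports `zero_motion` instead of a
break; the test suite asserts both.

## The sequential two-site equilibrium

The binding model is stepwise: `K_D1 = [P][Ag]/[PAg]`,
`K_D2 = [PAg][Ag]/[PAg2]`, chosen (over cumulative constants) because the
titration narrative is a first high-affinity and then a low-affinity
binding event. Substituting both equilibria into the peptide conservation
law leaves a single strictly increasing scalar equation in free Ag⁺ on
`[0, ag_total]`; `solve_species()` brackets it with `stats::uniroot` and
polishes with a few analytic Newton steps, then verifies both
conservation laws to 1e-9 relative and errors rather than returning an
inconsistent state. There are no random starts anywhere; the solver is
deterministic, and the test suite checks it against an independently
written bisection oracle on random parameter grids to 1e-6 relative.

## ESI-MS assignment, quantification and fitting

**Adducts.** Positive-mode metalated-peptide convention: each bound Ag⁺
contributes its own charge and the remaining charges are protons, so a
k-mer with n silvers at charge z sits at
`(k*M + n*m(Ag+) + (z-n)*m(H+))/z` and n > z has no ion (charge
deficit). Cation masses carry the electron correction; the average-mass
convention is the default because the quoted synthesis MWs are average
masses (the packaged residue table reproduces both quoted values within
±0.05 Da, the slack absorbing atomic-weight-table vintages).

**Assignment.** Every centroid is matched to the nearest theoretical m/z
within `tol_ppm` (default 10) over a (k, n, z) grid; ambiguous exact ties
are flagged and excluded from quantification rather than guessed. Note
the built-in degeneracy of the convention: a doubly protonated dimer at
z = 2 coincides exactly with the protonated monomer at z = 1, which is
why the default search range is z = 2:3 — appropriate for a ~2.2 kDa
peptide in an ion trap and free of that collision.

**Quantification.** Signal response is assumed proportional to species
concentration (configurable per-species response factors allow
sensitivity analyses). Areas are summed over all charge states per
(k, n) species; a k-mer contributes k peptide equivalents, and because
gas-phase dimers are nonspecific electrostatic artifacts they carry no
silver and feed the apo pool. Fractions are `f0, f1, f2` of peptide in
the apo, 1:1 and ≥2:1 states and always sum to 1.

**Fitting.** `fit_kds()` minimises the sum of squared fraction residuals
against the mass-balance model over `log(K_D1), log(K_D2)` with
Nelder-Mead from the fixed start (1 μM, 10 μM) plus one deterministic
restart. Fractions, not raw areas, are fitted so the result is invariant
to overall signal scale. When the peptide concentration far exceeds
K_D1 the first site is saturated at every point and the data bound K_D1
only from above; the fit probes this by doubling the estimate and
reports `kd1_identifiable = FALSE` when the objective moves by less than
1e-8, in which case `kd1_hat` should be read as an upper bound.

## What the synthetic data emulates — and what it does not

The NMR generator has two modes. *Equilibrium* mode is the fast-exchange
physics: each cross-peak of residue i sits at
`base + f1(r)*d1 + f2(r)*d2` with `f1, f2` the PAg/PAg₂ species
fractions from the solver, so `d1` is the 1:1 bound-state offset, `d2`
the full 2:1 offset, and every noiseless peak lies in the triangle of
the free and two bound positions. *Phenomenological* mode draws a
piecewise-linear path with an explicit vertex at `break_ratio`; it
exists because the observed direction change after 0.5 equivalents is a
statement about the data, and at 1 mM peptide a sequential model with a
sub-μM first constant would pin the kink near 1.0 equivalents instead —
the mode lets the detector be tested against the stated vertex without
arguing the chemistry. The `sp2-paper` preset uses it with the five
experimental ratios, two-mode vectors on 80His, 83Met, 84Val, 87His,
90Met and 91Met (turn angles 82–89°), gentle one-mode drifts elsewhere,
and saturating progress `r/(r+2)` after the vertex.

The MS generator converts isotherm concentrations into stick spectra at
exact theoretical m/z over z = 2:3, splitting each species' area equally
across its valid charge states, with `dimer_fraction = 0.3` of apo
peptide equivalents emitted as a z = 2 dimer (the experiments report the
apo peptide "mainly" as a dimer but give no number; 0.3 keeps both
monomer and dimer prominent). The `sp3-paper` preset stores the
experimental design — 100 μM peptide, ratios 0, 0.5, 1, 2 — with ground
truth K_D1 = 0.2 μM (the literature prior consistent with the < 1 μM
bound) and K_D2 = 24.5 μM. Both presets are noiseless by default because
the recovery checks are defined on the noiseless world; noise levels
(Gaussian 0.002 ppm per NMR axis, lognormal 5% CV on MS areas) are
conventions for test design, as no instrumental noise magnitudes are
published.

None of this emulates real spectra: no lineshapes, overlap, baseline or
phase artifacts, no intermediate-exchange broadening, no isotope
patterns (silver's two-isotope signature is deliberately out of scope),
and assignment is given, not inferred. A green recovery test therefore
establishes that the analysis stages are mutually consistent and
numerically correct — not that they would survive a crowded spectrum.

## Numerical conventions

- Seeds: every generator draws from one seeded RNG (`seed = 1722` by
  default); runs are bit-reproducible.
- Root finding: `uniroot` at tolerance `eps^0.75 * max(1, ag_total)` with
  ≤ 8 Newton polish iterations; mass balance enforced at 1e-9 relative.
- Optimisation: Nelder-Mead, `reltol = 1e-14`, 2000 iterations, one
  restart; log-parameterised so constants stay positive.
- Degenerate inputs: zero totals short-circuit the solver; empty MS files
  warn and return empty spectra; all-missing CSP groups are omitted with
  a warning; trajectories need ≥ 3 present points.
- Peak-list files are TSV/CSV with a fixed 6-column header; blank shift
  cells mean "cross-peak not visible", and series assemble the union of
  assignments with explicit `present = FALSE` gaps.

## Known limitations

- K_D1 is structurally unidentifiable from titrations run far above it;
  the fit flags this rather than pretending precision.
- The weak/medium/strong thresholds and the 30°/0.005 ppm trajectory
  thresholds are documented conventions, not published criteria.
- Which random-coil table vintage the original figures used is ambiguous;
  swap the TSV to match a specific reference if exact deltas matter.
- Dimer handling assumes all dimer signal is silver-free and nonspecific;
  silvered dimers, if present, would be assigned but not fitted.
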