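Package: silbind
Title: Silver-Peptide Binding Analysis from NMR and ESI-MS Titrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for metal-binding studies of SilE-derived model
    peptides titrated with silver(I). Reads assigned 2D NMR peak lists (TOCSY
    and 1H-13C HSQC) across a titration series and computes chemical shift
    perturbations with alpha-weighted carbon axes, groups signals and
    classifies weak/medium/strong movers, derives secondary 13C-alpha shifts
    against random-coil reference values, and detects direction changes in
    cross-peak titration trajectories that indicate multiple binding modes.
    For ESI-MS titrations it assigns centroided peaks to peptide/silver adduct
    species across charge states, quantifies mole fractions, and fits stepwise
    dissociation constants of a sequential two-site binding equilibrium. A
    synthetic-data module generates fast-exchange NMR titrations and stick
    ESI-MS spectra so every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
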