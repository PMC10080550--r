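# Shared fixtures and independent oracles for the test suite.

sp2_seq <- function() peptide_sequence("ADAHQKMVESHQRMMG", 77L)
sp3_seq <- function() peptide_sequence("AMNEHERAAVAHEFMNNGQ", 107L)

# minimal well-formed TOCSY peak data.frame
tiny_peaks <- function(f1 = c(8.10, 8.20, 8.30), f2 = c(4.20, 4.30, 4.40)) {
  data.frame(
    residue_index = 1:3,
    residue_type = c("A", "D", "A"),
    atom_f1 = "H",
    atom_f2 = "HA",
    f1_ppm = f1,
    f2_ppm = f2,
    stringsAsFactors = FALSE
  )
}

write_tiny_peaklist <- function(path, peaks = tiny_peaks(), sep = "\t") {
  header <- paste(c("residue_index", "residue_type", "atom_f1", "atom_f2",
                    "f1_ppm", "f2_ppm"), collapse = sep)
  rows <- apply(peaks, 1, function(r) paste(trimws(r), collapse = sep))
  writeLines(c(header, rows), path)
  path
}

# two-point TOCSY series for a 3-residue peptide with prescribed endpoint
# displacements (end = start + shift)
two_point_series <- function(shift_f1 = c(0, 0.03, 0), shift_f2 = c(0, 0.04, 0)) {
  seq3 <- peptide_sequence("ADA")
  start <- tiny_peaks()
  end <- start
  end$f1_ppm <- end$f1_ppm + shift_f1
  end$f2_ppm <- end$f2_ppm + shift_f2
  titration_series(seq3, list(
    peak_list("TOCSY", 0, start),
    peak_list("TOCSY", 10, end)
  ))
}

# Independent equilibrium oracle: plain bisection on free Ag, written from
# the mass-balance equations directly (no shared code with solve_species).
bisect_species_oracle <- function(kd1, kd2, p_total, ag_total, iters = 200) {
  bound_ag <- function(a) {
    d <- 1 + a / kd1 + a * a / (kd1 * kd2)
    pf <- p_total / d
    pf * a / kd1 + 2 * pf * a * a / (kd1 * kd2)
  }
  lo <- 0
  hi <- ag_total
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (mid + bound_ag(mid) - ag_total > 0) hi <- mid else lo <- mid
  }
  a <- (lo + hi) / 2
  d <- 1 + a / kd1 + a * a / (kd1 * kd2)
  pf <- p_total / d
  list(p_free = pf, pag = pf * a / kd1, pag2 = pf * a * a / (kd1 * kd2),
       ag_free = a)
}

# run the full assign -> quantify -> fit pipeline on a generated titration
ms_pipeline_fit <- function(config) {
  specs <- generate_ms_titration(config)
  quants <- lapply(specs, function(s) quantify(assign_species(s, config$sequence)))
  fit_kds(unname(quants))
}
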