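# Synthetic titration data with the statistical structure the analysis
# assumes, so every pipeline stage can be exercised by parameter recovery.
#
# NMR generator modes:
#   equilibrium      - fast-exchange physics: each cross-peak sits at the
#                      population-weighted average of free and bound
#                      positions, with site occupancies from the two-site
#                      equilibrium solver. Used for CSP and solver tests.
#   phenomenological - a piecewise-linear path with an explicit vertex at
#                      break_ratio, used to test the direction-change
#                      detector independently of any binding model.
#
# The MS generator turns isotherm species concentrations into stick spectra
# at theoretical adduct m/z values over a charge range, with a configurable
# share of the apo peptide appearing as a nonspecific gas-phase dimer.

.GAMMA_H_RES <- c("V", "M", "K", "Q", "E", "R", "I", "L")
.GAMMA_C_RES <- c("M", "K", "Q", "E", "R", "P", "I", "L")

# deterministic baseline chemical shifts (ppm) per atom/residue; small
# index-dependent offsets spread the peaks so assignments stay resolvable
.base_shift <- function(atom, residue_type, idx) {
  first <- substr(atom, 1, 1)
  pos <- substr(atom, 2, 2)
  if (first == "H") {
    if (pos == "") return(8.00 + 0.025 * idx)  # backbone amide
    switch(pos,
      "A" = 4.10 + 0.012 * idx,
      "B" = 1.70 + 0.011 * idx,
      "G" = 0.90 + 0.013 * idx,
      "D" = if (residue_type == "H") 7.05 + 0.005 * idx else 1.50 + 0.010 * idx,
      "E" = if (residue_type == "H") 7.75 + 0.005 * idx
            else if (residue_type == "M") 2.00 + 0.004 * idx
            else 2.90 + 0.010 * idx,
      8.00 + 0.025 * idx
    )
  } else {
    switch(pos,
      "A" = 52 + 0.4 * idx,
      "B" = if (residue_type == "A") 18.5 + 0.1 * idx else 31.5 + 0.15 * idx,
      "G" = if (residue_type %in% c("V", "T")) 21.0 + 0.1 * idx
            else 29.0 + 0.15 * idx,
      "D" = if (residue_type == "H") 119.5 + 0.1 * idx else 24.0 + 0.1 * idx,
      "E" = if (residue_type == "H") 136.5 + 0.1 * idx else 16.8 + 0.05 * idx,
      40 + 0.1 * idx
    )
  }
}

# template assignment set for a peptide (no Pro handling beyond amide drop)
.template_assignments <- function(sequence, spectrum_type) {
  res <- residue_letters(sequence)
  rows <- list()
  add <- function(i, t, a1, a2) {
    rows[[length(rows) + 1L]] <<- data.frame(
      residue_index = i, residue_type = t, atom_f1 = a1, atom_f2 = a2,
      stringsAsFactors = FALSE
    )
  }
  for (i in seq_along(res)) {
    t <- res[i]
    if (spectrum_type == "TOCSY") {
      if (t != "P") add(i, t, "H", "HA")
      if (t != "G") add(i, t, "HA", "HB")
      if (t != "P" && t %in% .GAMMA_H_RES) add(i, t, "H", "HG")
    } else {
      add(i, t, "CA", "HA")
      if (t != "G") add(i, t, "CB", "HB")
      if (t %in% .GAMMA_C_RES) add(i, t, "CG", "HG")
      if (t == "V") add(i, t, "CG1", "HG")
      if (t == "M") add(i, t, "CE", "HE")
      if (t == "H") {
        add(i, t, "CD", "HD")
        add(i, t, "CE", "HE")
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' NMR titration simulation configuration
#'
#' @param sequence A [peptide_sequence()] or one-letter string.
#' @param ratios Ag+:peptide ratios of the simulated series; must include 0.
#' @param spectrum_type `"TOCSY"` or `"HSQC_CH"`.
#' @param mode `"equilibrium"` (fast-exchange physics driven by a
#'   [binding_model()]) or `"phenomenological"` (piecewise path with a
#'   vertex at `break_ratio`).
#' @param site_shifts data.frame with columns `residue_index`, `d1_f1`,
#'   `d1_f2`, `d2_f1`, `d2_f2` (ppm): per-residue shift vectors of the two
#'   binding modes (equilibrium: bound-state offsets of the 1:1 and 2:1
#'   complexes relative to the free position; phenomenological:
#'   pre-/post-break direction vectors). Residues absent
#'   from the table do not move. A residue with a non-zero `d2` vector is a
#'   two-mode residue.
#' @param model A [binding_model()]; required in equilibrium mode.
#' @param p_total Total peptide concentration (uM) in equilibrium mode;
#'   default 1000 (the 1 mM NMR regime).
#' @param break_ratio Vertex ratio in phenomenological mode; must be one of
#'   `ratios`.
#' @param noise_sd Gaussian noise standard deviation per axis (ppm);
#'   default 0.002.
#' @param seed Integer RNG seed; default 1722.
#' @return List of class `nmr_sim_config`.
#' @export
nmr_sim_config <- function(sequence, ratios,
                           spectrum_type = c("TOCSY", "HSQC_CH"),
                           mode = c("equilibrium", "phenomenological"),
                           site_shifts, model = NULL, p_total = 1000,
                           break_ratio = NULL, noise_sd = 0.002,
                           seed = 1722) {
  spectrum_type <- match.arg(spectrum_type)
  mode <- match.arg(mode)
  if (is.character(sequence)) sequence <- peptide_sequence(sequence)
  stopifnot(inherits(sequence, "peptide_sequence"),
            is.numeric(ratios), length(ratios) >= 2L,
            noise_sd >= 0)
  ratios <- sort(unique(ratios))
  if (!any(ratios == 0)) stop("ratios must include the 0.0 reference point")
  site_shifts <- as.data.frame(site_shifts, stringsAsFactors = FALSE)
  need <- c("residue_index", "d1_f1", "d1_f2", "d2_f1", "d2_f2")
  stopifnot(all(need %in% names(site_shifts)))
  if (any(site_shifts$residue_index < 1L |
            site_shifts$residue_index > length(sequence))) {
    stop("site_shifts references residues outside the sequence")
  }
  if (mode == "equilibrium") {
    stopifnot(inherits(model, "binding_model"), p_total > 0)
  } else {
    if (is.null(break_ratio) || !any(abs(ratios - break_ratio) < 1e-12)) {
      stop("phenomenological mode needs break_ratio equal to one of the ratios")
    }
  }
  structure(
    list(sequence = sequence, ratios = ratios,
         spectrum_type = spectrum_type, mode = mode,
         site_shifts = site_shifts, model = model, p_total = p_total,
         break_ratio = break_ratio, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "nmr_sim_config"
  )
}

#' Two-mode assignments of a simulated NMR series
#'
#' Lists the cross-peak assignments whose residue carries a second-mode
#' shift vector in the configuration, i.e. the trajectories expected to
#' show a direction change.
#'
#' @param config An [nmr_sim_config()].
#' @return data.frame with `residue_index`, `residue_type`, `atom_f1`,
#'   `atom_f2`.
#' @export
sim_two_mode_assignments <- function(config) {
  stopifnot(inherits(config, "nmr_sim_config"))
  ss <- config$site_shifts
  two <- ss$residue_index[ss$d2_f1 != 0 | ss$d2_f2 != 0]
  tmpl <- .template_assignments(config$sequence, config$spectrum_type)
  out <- tmpl[tmpl$residue_index %in% two, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# saturating progress function for the phenomenological path
.sat_progress <- function(r) r / (r + 2)

#' Generate a synthetic NMR titration series
#'
#' In equilibrium mode each cross-peak of residue i sits, at ratio r, at
#' the fast-exchange population-weighted average
#' `base + f1(r) * d1_i + f2(r) * d2_i`, where `f1 = [PAg] / p_total` and
#' `f2 = [PAg2] / p_total` are the species fractions from
#' [solve_species()]. `d1` is therefore the bound-state offset of the 1:1
#' complex and `d2` the full offset of the 2:1 complex, so every noiseless
#' peak lies in the triangle spanned by the free position and the two
#' bound positions. In phenomenological mode the peak walks
#' linearly along `d1` up to `break_ratio` and then along `d2` with a
#' saturating progress, producing a single vertex at `break_ratio`.
#' Seeded Gaussian noise is added per axis.
#'
#' @param config An [nmr_sim_config()].
#' @return A [titration_series()].
#' @export
generate_nmr_series <- function(config) {
  stopifnot(inherits(config, "nmr_sim_config"))
  set.seed(config$seed)
  tmpl <- .template_assignments(config$sequence, config$spectrum_type)
  base_f1 <- mapply(.base_shift, tmpl$atom_f1, tmpl$residue_type,
                    tmpl$residue_index)
  base_f2 <- mapply(.base_shift, tmpl$atom_f2, tmpl$residue_type,
                    tmpl$residue_index)
  ss <- config$site_shifts
  i <- match(tmpl$residue_index, ss$residue_index)
  d1 <- cbind(ifelse(is.na(i), 0, ss$d1_f1[i]),
              ifelse(is.na(i), 0, ss$d1_f2[i]))
  d2 <- cbind(ifelse(is.na(i), 0, ss$d2_f1[i]),
              ifelse(is.na(i), 0, ss$d2_f2[i]))
  two_mode <- d2[, 1] != 0 | d2[, 2] != 0
  r_max <- max(config$ratios)
  weight_at <- function(r) {
    # returns per-peak matrix of (w1, w2) weights on d1 and d2
    if (config$mode == "equilibrium") {
      s <- solve_species(config$model, config$p_total,
                         r * config$p_total)
      f1 <- s$pag / config$p_total
      f2 <- s$pag2 / config$p_total
      cbind(rep(f1, nrow(tmpl)), rep(f2, nrow(tmpl)))
    } else {
      br <- config$break_ratio
      w1_two <- pmin(r, br) / br
      w2_two <- if (r <= br) 0 else {
        (.sat_progress(r) - .sat_progress(br)) /
          (.sat_progress(r_max) - .sat_progress(br))
      }
      w1_one <- .sat_progress(r) / .sat_progress(r_max)
      cbind(ifelse(two_mode, w1_two, w1_one),
            ifelse(two_mode, w2_two, 0))
    }
  }
  points <- lapply(config$ratios, function(r) {
    w <- weight_at(r)
    f1 <- base_f1 + w[, 1] * d1[, 1] + w[, 2] * d2[, 1]
    f2 <- base_f2 + w[, 1] * d1[, 2] + w[, 2] * d2[, 2]
    if (config$noise_sd > 0) {
      f1 <- f1 + stats::rnorm(length(f1), sd = config$noise_sd)
      f2 <- f2 + stats::rnorm(length(f2), sd = config$noise_sd)
    }
    peaks <- cbind(tmpl, data.frame(f1_ppm = f1, f2_ppm = f2,
                                    present = TRUE))
    peak_list(config$spectrum_type, r, peaks)
  })
  titration_series(config$sequence, points)
}

#' ESI-MS titration simulation configuration
#'
#' @param sequence A [peptide_sequence()] or one-letter string (sets the
#'   monomer mass).
#' @param model A [binding_model()] giving the ground-truth stepwise
#'   dissociation constants.
#' @param p_total Total peptide concentration (uM), default 100.
#' @param ratios Ag+:peptide ratios, default `c(0, 0.5, 1, 2)`.
#' @param z_range Charge states emitted per species, default 2:3.
#' @param dimer_fraction Share of apo peptide equivalents detected as a
#'   nonspecific gas-phase dimer, in [0, 1); default 0.3.
#' @param response_factors Optional named vector (`"k1n0"`, `"k1n1"`, ...)
#'   of relative response factors; default all 1.
#' @param noise_cv Multiplicative (lognormal) area noise coefficient of
#'   variation; default 0 (noiseless).
#' @param seed Integer RNG seed; default 1722.
#' @return List of class `ms_sim_config`.
#' @export
ms_sim_config <- function(sequence, model, p_total = 100,
                          ratios = c(0, 0.5, 1, 2), z_range = 2:3,
                          dimer_fraction = 0.3, response_factors = NULL,
                          noise_cv = 0, seed = 1722) {
  if (is.character(sequence)) sequence <- peptide_sequence(sequence)
  stopifnot(inherits(sequence, "peptide_sequence"),
            inherits(model, "binding_model"),
            p_total > 0, all(ratios >= 0),
            dimer_fraction >= 0, dimer_fraction < 1,
            noise_cv >= 0)
  structure(
    list(sequence = sequence, model = model, p_total = p_total,
         ratios = sort(unique(ratios)), z_range = as.integer(z_range),
         dimer_fraction = dimer_fraction,
         response_factors = response_factors,
         noise_cv = noise_cv, seed = as.integer(seed)),
    class = "ms_sim_config"
  )
}

#' Generate a synthetic ESI-MS titration
#'
#' For each ratio the two-site equilibrium is solved and the species
#' (apo monomer, apo dimer, singly and doubly silvered monomer) are
#' emitted as stick peaks at their theoretical m/z over the charge range,
#' with areas proportional to concentration times response factor split
#' equally across valid charge states (dimers appear at z = 2 only).
#' Optional multiplicative lognormal noise perturbs the areas; m/z values
#' are exact, so a noiseless round trip through [assign_species()] at
#' 10 ppm recovers the generated species set exactly.
#'
#' @param config An [ms_sim_config()].
#' @return Named list of [ms_spectrum()] objects, one per ratio.
#' @export
generate_ms_titration <- function(config) {
  stopifnot(inherits(config, "ms_sim_config"))
  set.seed(config$seed)
  m <- peptide_mass(config$sequence, mode = "average")
  rf <- function(k, n) {
    if (is.null(config$response_factors)) return(1)
    v <- config$response_factors[[paste0("k", k, "n", n)]]
    if (is.null(v) || is.na(v)) 1 else v
  }
  out <- lapply(config$ratios, function(r) {
    ag_total <- r * config$p_total
    s <- solve_species(config$model, config$p_total, ag_total)
    df <- config$dimer_fraction
    species <- data.frame(
      k = c(1L, 2L, 1L, 1L),
      n = c(0L, 0L, 1L, 2L),
      conc = c((1 - df) * s$p_free, df * s$p_free / 2, s$pag, s$pag2)
    )
    species <- species[species$conc > 0, , drop = FALSE]
    rows <- list()
    for (j in seq_len(nrow(species))) {
      k <- species$k[j]
      n <- species$n[j]
      zs <- if (k == 2L) intersect(config$z_range, 2L) else
        config$z_range[config$z_range >= n]
      if (length(zs) == 0L) next
      area_each <- species$conc[j] * rf(k, n) / length(zs)
      for (z in zs) {
        rows[[length(rows) + 1L]] <- data.frame(
          mz = theoretical_mz(m, k, n, z), area = area_each
        )
      }
    }
    peaks <- do.call(rbind, rows)
    if (config$noise_cv > 0) {
      sdlog <- sqrt(log(1 + config$noise_cv^2))
      peaks$area <- peaks$area *
        stats::rlnorm(nrow(peaks), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    ms_spectrum(config$p_total, ag_total, peaks)
  })
  names(out) <- paste0("ratio_", config$ratios)
  out
}

#' Load a packaged simulation preset
#'
#' Presets encode the experimental designs this package is built around:
#' `"sp2-paper"` is a five-point TOCSY titration (ratios 0, 0.1, 0.5, 3,
#' 10) of the 16-residue fragment SP2 with a direction change after 0.5
#' equivalents at the binding-motif residues; `"sp3-paper"` is a four-point
#' ESI-MS titration (100 uM peptide; ratios 0, 0.5, 1, 2) of the
#' 19-residue fragment SP3 with stepwise dissociation constants 0.2 and
#' 24.5 uM. Both default to noiseless output.
#'
#' @param name Preset name, `"sp2-paper"` or `"sp3-paper"`.
#' @param seed Optional seed overriding the preset's stored default.
#' @return An [nmr_sim_config()] or [ms_sim_config()].
#' @export
sim_preset <- function(name = c("sp2-paper", "sp3-paper"), seed = NULL) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".json"),
                      package = "silbind")
  if (path == "") stop("preset file not found: ", name)
  p <- jsonlite::fromJSON(path)
  if (!is.null(seed)) p$seed <- seed
  seq <- peptide_sequence(p$sequence, p$numbering_offset)
  if (p$kind == "nmr") {
    nmr_sim_config(
      sequence = seq, ratios = p$ratios, spectrum_type = p$spectrum_type,
      mode = p$mode, site_shifts = p$site_shifts,
      break_ratio = p$break_ratio, noise_sd = p$noise_sd, seed = p$seed
    )
  } else {
    ms_sim_config(
      sequence = seq, model = binding_model(p$kd1, p$kd2),
      p_total = p$p_total, ratios = p$ratios, z_range = p$z_range,
      dimer_fraction = p$dimer_fraction, noise_cv = p$noise_cv,
      seed = p$seed
    )
  }
}
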