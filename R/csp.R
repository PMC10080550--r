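# Chemical shift perturbation mapping: per-cross-peak displacement between
# a reference and an endpoint titration spectrum, signal grouping, and
# weak/medium/strong mover classification relative to per-group statistics.

# Methyl carbons (residue:carbon) whose cross-peaks form the CH3 group.
.METHYL_CARBONS <- c(
  "A:CB", "V:CG1", "V:CG2", "T:CG2", "L:CD1", "L:CD2", "I:CG2", "I:CD1",
  "M:CE"
)

#' CSP configuration
#'
#' @param alpha Carbon-axis scaling coefficient for heteronuclear CSPs
#'   (dimensionless). The conventional literature value 0.3 is the default.
#' @param reference_ratio Titration ratio used as the CSP start point.
#' @param endpoint_ratio Titration ratio used as the CSP end point.
#' @param sigma Per-group standard-deviation convention: `"population"`
#'   (divide by n, default) or `"sample"` (n - 1).
#' @return A list of class `csp_config`.
#' @export
csp_config <- function(alpha = 0.3, reference_ratio = 0, endpoint_ratio = 10,
                       sigma = c("population", "sample")) {
  sigma <- match.arg(sigma)
  stopifnot(is.numeric(alpha), alpha > 0,
            reference_ratio < endpoint_ratio)
  structure(
    list(alpha = alpha, reference_ratio = reference_ratio,
         endpoint_ratio = endpoint_ratio, sigma = sigma),
    class = "csp_config"
  )
}

#' Homonuclear (TOCSY) chemical shift perturbation
#'
#' Euclidean displacement of a proton-proton cross-peak between two spectra:
#' `sqrt(d_F1^2 + d_F2^2)` with both axes in 1H ppm.
#'
#' @param d_f1,d_f2 Chemical-shift differences (end minus start) on the two
#'   proton axes, in ppm. `NA` in either axis yields `NA` (missing peak).
#' @return CSP in ppm (>= 0), vectorised.
#' @examples
#' csp_tocsy(0.03, 0.04) # 0.05
#' @export
csp_tocsy <- function(d_f1, d_f2) {
  sqrt(d_f1^2 + d_f2^2)
}

#' Heteronuclear (1H-13C HSQC) chemical shift perturbation
#'
#' The carbon axis spans a far wider ppm range than the proton axis, so its
#' squared displacement is scaled by `alpha` before combining:
#' `sqrt(d_H^2 + alpha * d_C^2)`.
#'
#' @param d_h Proton-axis shift difference (ppm).
#' @param d_c Carbon-axis shift difference (ppm).
#' @param alpha Carbon scaling coefficient (> 0), default 0.3.
#' @return CSP in ppm (>= 0), vectorised.
#' @examples
#' csp_hsqc(0.1, 0.2) # sqrt(0.01 + 0.3 * 0.04)
#' @export
csp_hsqc <- function(d_h, d_c, alpha = 0.3) {
  stopifnot(alpha > 0)
  sqrt(d_h^2 + alpha * d_c^2)
}

#' Signal group of an assigned cross-peak
#'
#' HSQC cross-peaks fall into four groups by the carbon atom: `CA_HA`,
#' `CB_HB`, `CG_HG` (which also absorbs the rarer non-methyl side-chain
#' carbons beyond gamma, e.g. histidine CD/CE) and `CH3` for methyl carbons.
#' TOCSY cross-peaks are grouped as backbone `TOCSY_NH_HA` versus
#' `TOCSY_OTHER`.
#'
#' @param spectrum_type `"TOCSY"` or `"HSQC_CH"`.
#' @param residue_type One-letter residue codes.
#' @param atom_f1,atom_f2 Atom names of the two axes.
#' @return Character vector of group labels.
#' @export
signal_group <- function(spectrum_type, residue_type, atom_f1, atom_f2) {
  if (spectrum_type == "TOCSY") {
    nh_ha <- (atom_f1 == "H" & atom_f2 == "HA") |
      (atom_f1 == "HA" & atom_f2 == "H")
    return(ifelse(nh_ha, "TOCSY_NH_HA", "TOCSY_OTHER"))
  }
  carbon <- ifelse(startsWith(atom_f1, "C"), atom_f1, atom_f2)
  methyl <- paste(residue_type, carbon, sep = ":") %in% .METHYL_CARBONS
  pos <- substr(carbon, 2, 2)
  ifelse(methyl, "CH3",
         ifelse(pos == "A", "CA_HA",
                ifelse(pos == "B", "CB_HB", "CG_HG")))
}

#' Compute the CSP table for a titration series
#'
#' For every assignment in the series, the displacement between the
#' reference-ratio and endpoint-ratio spectra is reduced to a single CSP
#' value (TOCSY: proton-proton Euclidean distance; HSQC: alpha-weighted).
#' Assignments whose cross-peak is absent at either endpoint get `csp = NA`
#' and `mover_class = "missing"`.
#'
#' @param series A [titration_series()].
#' @param config A [csp_config()].
#' @return data.frame of class `csp_table` with one row per assignment:
#'   `residue_index`, `residue_label`, `residue_type`, `atom_f1`, `atom_f2`,
#'   `csp`, `group`, `mover_class`.
#' @export
compute_csp_table <- function(series, config = csp_config()) {
  stopifnot(inherits(series, "titration_series"),
            inherits(config, "csp_config"))
  start <- series_point(series, config$reference_ratio)
  end <- series_point(series, config$endpoint_ratio)
  s <- start$peaks
  e <- end$peaks
  ok <- s$present & e$present
  d1 <- e$f1_ppm - s$f1_ppm
  d2 <- e$f2_ppm - s$f2_ppm
  if (series$spectrum_type == "TOCSY") {
    csp <- csp_tocsy(d1, d2)
  } else {
    # HSQC_CH convention: F1 carbon, F2 proton
    csp <- csp_hsqc(d2, d1, alpha = config$alpha)
  }
  csp[!ok] <- NA_real_
  out <- data.frame(
    residue_index = s$residue_index,
    residue_label = residue_label(series$sequence, s$residue_index),
    residue_type = s$residue_type,
    atom_f1 = s$atom_f1,
    atom_f2 = s$atom_f2,
    csp = csp,
    group = signal_group(series$spectrum_type, s$residue_type,
                         s$atom_f1, s$atom_f2),
    mover_class = ifelse(ok, NA_character_, "missing"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("csp_table", "data.frame")
  out
}

#' Per-group CSP mean and standard deviation
#'
#' Computed over non-missing records only; all-missing groups are omitted
#' with a warning.
#'
#' @param records A `csp_table` from [compute_csp_table()].
#' @param sigma `"population"` (n denominator, default) or `"sample"`.
#' @return data.frame with columns `group`, `mean`, `sigma`, `n`.
#' @export
group_stats <- function(records, sigma = c("population", "sample")) {
  sigma <- match.arg(sigma)
  ok <- !is.na(records$csp)
  groups <- unique(records$group)
  empty <- setdiff(groups, unique(records$group[ok]))
  if (length(empty) > 0L) {
    warning("group(s) with no observable CSPs omitted: ",
            paste(empty, collapse = ", "))
  }
  r <- records[ok, , drop = FALSE]
  if (nrow(r) == 0L) stop("no non-missing CSP records")
  agg <- lapply(split(r$csp, r$group), function(v) {
    n <- length(v)
    m <- mean(v)
    s2 <- sum((v - m)^2) / if (sigma == "population") n else max(n - 1L, 1L)
    c(mean = m, sigma = sqrt(s2), n = n)
  })
  out <- data.frame(
    group = names(agg),
    mean = vapply(agg, `[[`, numeric(1), "mean"),
    sigma = vapply(agg, `[[`, numeric(1), "sigma"),
    n = vapply(agg, `[[`, numeric(1), "n"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Classify weak/medium/strong movers within each signal group
#'
#' A record with CSP below the group mean is a weak mover, at or above the
#' mean but below mean + sigma a medium mover, and at or above mean + sigma
#' a strong mover (closed lower bounds, so a CSP exactly at the mean is
#' medium and exactly at mean + sigma is strong). Missing records keep
#' `mover_class = "missing"`.
#'
#' @param records A `csp_table` from [compute_csp_table()].
#' @param stats Optional precomputed [group_stats()]; computed if omitted.
#' @return `records` with `mover_class` filled in.
#' @export
classify_movers <- function(records, stats = NULL) {
  if (is.null(stats)) stats <- group_stats(records)
  i <- match(records$group, stats$group)
  mu <- stats$mean[i]
  sg <- stats$sigma[i]
  cls <- ifelse(records$csp < mu, "weak",
                ifelse(records$csp < mu + sg, "medium", "strong"))
  # sigma = 0 boundary: all CSPs equal the mean -> medium by convention
  cls[!is.na(records$csp) & !is.na(sg) & sg == 0 & records$csp == mu] <- "medium"
  records$mover_class <- ifelse(is.na(records$csp), "missing", cls)
  records
}
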