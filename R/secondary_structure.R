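# Secondary 13C-alpha shifts against random-coil reference values, and the
# ideal helical-wheel check used to reason about helix-face register.

#' Load a random-coil 13C-alpha reference table
#'
#' The packaged default is a standard literature table of random-coil
#' 13C-alpha shifts for the 20 amino acids (referenced to DSS). Users can
#' supply their own two-column TSV (`residue_type`, `delta_rc_ppm`) to swap
#' reference vintages.
#'
#' @param path Optional path to a replacement TSV; default: packaged table.
#' @return Named numeric vector, one ppm value per one-letter residue code.
#' @export
random_coil_ca <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "random_coil_ca13.tsv", package = "silbind")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("residue_type", "delta_rc_ppm") %in% names(tab)))
  v <- stats::setNames(as.numeric(tab$delta_rc_ppm), toupper(tab$residue_type))
  missing <- setdiff(names(.AA_MASS_AVG), names(v))
  if (length(missing) > 0L) {
    stop("random-coil table lacks residue(s): ", paste(missing, collapse = ", "))
  }
  if (any(v < 40 | v > 70)) {
    stop("random-coil 13C-alpha values outside the plausible 40-70 ppm range")
  }
  v
}

#' Secondary 13C-alpha shifts at one titration point
#'
#' For each residue whose CA/HA cross-peak is present at the requested
#' ratio, reports `delta = delta_obs(13CA) - delta_rc`, the observed carbon
#' shift minus the random-coil reference. Positive deltas indicate helical
#' tendency.
#'
#' @param series An HSQC [titration_series()] (F1 carbon, F2 proton).
#' @param table Named numeric vector from [random_coil_ca()].
#' @param ratio Titration ratio at which to evaluate.
#' @return data.frame with `residue_index`, `residue_label`, `residue_type`,
#'   `ratio`, `delta_obs`, `delta_rc`, `delta`.
#' @export
secondary_shifts <- function(series, table = random_coil_ca(), ratio) {
  stopifnot(inherits(series, "titration_series"))
  if (series$spectrum_type != "HSQC_CH") {
    stop("secondary shifts require a 1H-13C HSQC series")
  }
  pl <- series_point(series, ratio)
  p <- pl$peaks
  sel <- p$atom_f1 == "CA" & p$present
  p <- p[sel, , drop = FALSE]
  unknown <- setdiff(unique(p$residue_type), names(table))
  if (length(unknown) > 0L) {
    stop("residue type(s) absent from random-coil table: ",
         paste(unknown, collapse = ", "))
  }
  rc <- table[p$residue_type]
  out <- data.frame(
    residue_index = p$residue_index,
    residue_label = residue_label(series$sequence, p$residue_index),
    residue_type = p$residue_type,
    ratio = ratio,
    delta_obs = p$f1_ppm,
    delta_rc = as.numeric(rc),
    delta = p$f1_ppm - as.numeric(rc),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Are two residues on the same face of an ideal alpha-helix?
#'
#' Uses the ideal helical wheel (100 degrees of rotation per residue): the
#' angular separation of residues i and j is `100 * |i - j| mod 360`,
#' folded into [0, 180]. They are called same-face when that separation is
#' within `tolerance_deg` of zero. The default tolerance of 80 degrees
#' admits both the i+3 (60 degrees) and i+4 (40 degrees) registers that
#' place side chains on one helix face, while rejecting i+2 (160 degrees).
#' Note that adjacent residues (i+1, 100 degrees) are NOT same-face under
#' this rule.
#'
#' @param i,j Residue indices (any common numbering).
#' @param tolerance_deg Angular tolerance in degrees, default 80.
#' @return Logical, vectorised over `i`/`j`.
#' @examples
#' same_helix_face(80, 83) # TRUE  (i+3)
#' same_helix_face(87, 91) # TRUE  (i+4)
#' same_helix_face(80, 82) # FALSE (i+2)
#' @export
same_helix_face <- function(i, j, tolerance_deg = 80) {
  stopifnot(all(i != j), tolerance_deg >= 0)
  ang <- (100 * abs(i - j)) %% 360
  sep <- pmin(ang, 360 - ang)
  sep <= tolerance_deg
}
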