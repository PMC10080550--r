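# Peak lists, titration series and MS spectra: constructors, readers, writers.
#
# Peak-list files are plain TSV (or CSV) with the 6-column header
#   residue_index  residue_type  atom_f1  atom_f2  f1_ppm  f2_ppm
# one file per titration point. Blank shift cells mark cross-peaks that are
# not visible at that titration point; they are carried as present = FALSE
# rather than dropped, so downstream stages must handle them explicitly.

.PEAKLIST_COLS <- c(
  "residue_index", "residue_type", "atom_f1", "atom_f2", "f1_ppm", "f2_ppm"
)

# Controlled atom-name vocabulary: backbone amide proton "H", or a proton /
# carbon name built from a Greek-position letter with an optional branch
# digit (HA, HB, HG1, CA, CB, CG2, CD, CE, ...).
.ATOM_RE <- "^(H|[HC][ABGDEZ][123]?)$"

is_valid_atom <- function(atom) grepl(.ATOM_RE, atom)

.assignment_key <- function(peaks) {
  paste(peaks$residue_index, peaks$atom_f1, peaks$atom_f2, sep = ":")
}

#' Construct a 2D peak list
#'
#' One assigned 2D spectrum at a single titration point. `peaks` must carry
#' the columns `residue_index`, `residue_type`, `atom_f1`, `atom_f2`,
#' `f1_ppm`, `f2_ppm` and optionally `present` (defaults to shifts being
#' non-missing). For `HSQC_CH` lists the F1 axis is the carbon and F2 the
#' attached proton; TOCSY lists are proton-proton.
#'
#' @param spectrum_type `"TOCSY"` or `"HSQC_CH"`.
#' @param ratio Ag+:peptide concentration ratio (equivalents), >= 0.
#' @param peaks data.frame of assigned cross-peaks.
#' @return An object of class `peak_list`.
#' @export
peak_list <- function(spectrum_type = c("TOCSY", "HSQC_CH"), ratio, peaks) {
  spectrum_type <- match.arg(spectrum_type)
  stopifnot(is.numeric(ratio), length(ratio) == 1L, is.finite(ratio))
  if (ratio < 0) stop("titration ratio must be >= 0")
  peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.PEAKLIST_COLS, names(peaks))
  if (length(missing_cols) > 0L) {
    stop("peaks is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"present" %in% names(peaks)) {
    peaks$present <- is.finite(peaks$f1_ppm) & is.finite(peaks$f2_ppm)
  }
  peaks <- peaks[c(.PEAKLIST_COLS, "present")]
  peaks$residue_index <- as.integer(peaks$residue_index)
  bad_atoms <- unique(c(peaks$atom_f1, peaks$atom_f2))
  bad_atoms <- bad_atoms[!is_valid_atom(bad_atoms)]
  if (length(bad_atoms) > 0L) {
    stop("atom name(s) outside the controlled vocabulary: ",
         paste(bad_atoms, collapse = ", "))
  }
  key <- .assignment_key(peaks)
  if (anyDuplicated(key)) {
    stop("duplicate assignment(s) in peak list: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  pres <- which(peaks$present)
  if (any(!is.finite(peaks$f1_ppm[pres])) ||
      any(!is.finite(peaks$f2_ppm[pres]))) {
    stop("present peaks must have finite chemical shifts")
  }
  .check_ppm_window <- function(ppm, atoms, axis) {
    is_c <- startsWith(atoms, "C")
    lo <- ifelse(is_c, 0, -2)
    hi <- ifelse(is_c, 190, 12)
    bad <- which(ppm < lo | ppm > hi)
    if (length(bad) > 0L) {
      stop(sprintf("%s ppm value out of plausible window at row %d (%g)",
                   axis, bad[1], ppm[bad[1]]))
    }
  }
  .check_ppm_window(peaks$f1_ppm[pres], peaks$atom_f1[pres], "f1")
  .check_ppm_window(peaks$f2_ppm[pres], peaks$atom_f2[pres], "f2")
  if (spectrum_type == "TOCSY" &&
      any(startsWith(c(peaks$atom_f1, peaks$atom_f2), "C"))) {
    stop("TOCSY peak lists must be proton-proton")
  }
  rownames(peaks) <- NULL
  structure(
    list(spectrum_type = spectrum_type, ratio = ratio, peaks = peaks),
    class = "peak_list"
  )
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %s at ratio %.3g: %d peaks (%d present)\n",
              x$spectrum_type, x$ratio, nrow(x$peaks), sum(x$peaks$present)))
  invisible(x)
}

.parse_delim_table <- function(path, expected_cols) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) return(NULL)
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  header <- trimws(strsplit(lines[1], sep, fixed = TRUE)[[1]])
  if (!identical(header, expected_cols)) {
    stop("unexpected header in ", path, "; expected: ",
         paste(expected_cols, collapse = sep))
  }
  if (length(lines) == 1L) {
    out <- as.data.frame(
      stats::setNames(rep(list(character(0)), length(header)), header),
      stringsAsFactors = FALSE
    )
    return(out)
  }
  rows <- strsplit(lines[-1], sep, fixed = TRUE)
  n_ok <- vapply(rows, length, integer(1))
  bad <- which(n_ok > length(header))
  if (length(bad) > 0L) {
    stop(sprintf("malformed row at line %d of %s: %d fields (expected %d)",
                 bad[1] + 1L, path, n_ok[bad[1]], length(header)))
  }
  # a row ending in an empty final cell drops it on split; pad back
  rows <- lapply(rows, function(r) c(r, rep("", length(header) - length(r))))
  mat <- do.call(rbind, rows)
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- header
  out[] <- lapply(out, trimws)
  out
}

#' Read an assigned 2D peak list from TSV/CSV
#'
#' Parses one titration point. Rows with a blank `f1_ppm` or `f2_ppm` cell
#' become `present = FALSE` peaks (cross-peak not visible in that spectrum).
#'
#' @param path Path to a TSV or CSV file with the documented 6-column header.
#' @param spectrum_type `"TOCSY"` or `"HSQC_CH"`.
#' @param ratio Ag+:peptide ratio of this titration point.
#' @return A [peak_list()].
#' @export
read_peaklist <- function(path, spectrum_type = c("TOCSY", "HSQC_CH"), ratio) {
  spectrum_type <- match.arg(spectrum_type)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- .parse_delim_table(path, .PEAKLIST_COLS)
  if (is.null(tab) || nrow(tab) == 0L) {
    stop("peak list file is empty: ", path)
  }
  num <- function(x, col) {
    blank <- x == "" | toupper(x) == "NA"
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!blank & is.na(v))
    if (length(bad) > 0L) {
      stop(sprintf("malformed numeric value in column %s at line %d of %s",
                   col, bad[1] + 1L, path))
    }
    v
  }
  ri <- num(tab$residue_index, "residue_index")
  if (any(is.na(ri))) stop("residue_index must not be blank in ", path)
  peaks <- data.frame(
    residue_index = as.integer(ri),
    residue_type = toupper(tab$residue_type),
    atom_f1 = tab$atom_f1,
    atom_f2 = tab$atom_f2,
    f1_ppm = num(tab$f1_ppm, "f1_ppm"),
    f2_ppm = num(tab$f2_ppm, "f2_ppm"),
    stringsAsFactors = FALSE
  )
  peaks$present <- !is.na(peaks$f1_ppm) & !is.na(peaks$f2_ppm)
  peak_list(spectrum_type, ratio, peaks)
}

#' Write a peak list to TSV
#'
#' Inverse of [read_peaklist()]: `present = FALSE` peaks are written with
#' blank shift cells. Numeric fields are written with enough digits for a
#' lossless round trip at typical peak-list precision.
#'
#' @param x A [peak_list()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(x, path) {
  stopifnot(inherits(x, "peak_list"))
  p <- x$peaks
  fmt <- function(v, pres) ifelse(pres, formatC(v, digits = 6, format = "f"), "")
  tab <- data.frame(
    residue_index = p$residue_index,
    residue_type = p$residue_type,
    atom_f1 = p$atom_f1,
    atom_f2 = p$atom_f2,
    f1_ppm = fmt(p$f1_ppm, p$present),
    f2_ppm = fmt(p$f2_ppm, p$present),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a titration series from peak lists
#'
#' Orders peak lists by increasing Ag+:peptide ratio and reconciles the
#' assignments: the union of all assignments is imposed on every point, with
#' peaks missing at a point carried as `present = FALSE`.
#'
#' @param sequence A [peptide_sequence()].
#' @param peak_lists List of [peak_list()] objects, all of one spectrum type.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(sequence, peak_lists) {
  stopifnot(inherits(sequence, "peptide_sequence"), length(peak_lists) >= 2L)
  for (pl in peak_lists) stopifnot(inherits(pl, "peak_list"))
  types <- vapply(peak_lists, function(p) p$spectrum_type, character(1))
  if (length(unique(types)) > 1L) {
    stop("all peak lists in a series must share one spectrum type")
  }
  ratios <- vapply(peak_lists, function(p) p$ratio, numeric(1))
  if (anyDuplicated(ratios)) {
    stop("titration ratios must be unique; got: ",
         paste(sort(ratios), collapse = ", "))
  }
  ord <- order(ratios)
  peak_lists <- peak_lists[ord]
  ratios <- ratios[ord]
  if (ratios[1] != 0) {
    warning("series has no 0.0 reference point; first ratio is ", ratios[1])
  }
  n_res <- length(sequence)
  # union of assignments across points, in first-seen order
  univ <- NULL
  for (pl in peak_lists) {
    p <- pl$peaks[.PEAKLIST_COLS[1:4]]
    univ <- if (is.null(univ)) p else rbind(univ, p)
  }
  univ <- univ[!duplicated(.assignment_key(univ)), , drop = FALSE]
  if (any(univ$residue_index < 1L | univ$residue_index > n_res)) {
    stop("assignment residue_index outside the peptide sequence")
  }
  seq_res <- residue_letters(sequence)
  mismatch <- univ$residue_type != seq_res[univ$residue_index]
  if (any(mismatch)) {
    stop("assignment residue_type disagrees with the sequence at index ",
         univ$residue_index[which(mismatch)[1]])
  }
  key_u <- .assignment_key(univ)
  points <- lapply(peak_lists, function(pl) {
    p <- pl$peaks
    idx <- match(key_u, .assignment_key(p))
    out <- univ
    out$f1_ppm <- p$f1_ppm[idx]
    out$f2_ppm <- p$f2_ppm[idx]
    out$present <- !is.na(idx) & p$present[ifelse(is.na(idx), 1L, idx)]
    out$f1_ppm[!out$present] <- NA_real_
    out$f2_ppm[!out$present] <- NA_real_
    rownames(out) <- NULL
    peak_list(pl$spectrum_type, pl$ratio, out)
  })
  structure(
    list(
      sequence = sequence,
      spectrum_type = types[1],
      ratios = ratios,
      points = points
    ),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "<titration_series> %s, %d points (ratios %s), %d assignments, peptide %s\n",
    x$spectrum_type, length(x$points),
    paste(x$ratios, collapse = ", "),
    nrow(x$points[[1]]$peaks), x$sequence$one_letter
  ))
  invisible(x)
}

#' Read a titration series from peak-list files
#'
#' @param paths Character vector of peak-list file paths (>= 2).
#' @param ratios Numeric vector of Ag+:peptide ratios, one per file.
#' @param spectrum_type `"TOCSY"` or `"HSQC_CH"` (shared by all files).
#' @param sequence A [peptide_sequence()].
#' @return A [titration_series()].
#' @export
read_series <- function(paths, ratios, spectrum_type = c("TOCSY", "HSQC_CH"),
                        sequence) {
  spectrum_type <- match.arg(spectrum_type)
  stopifnot(length(paths) == length(ratios), length(paths) >= 2L)
  pls <- Map(function(p, r) read_peaklist(p, spectrum_type, r), paths, ratios)
  titration_series(sequence, unname(pls))
}

#' Extract one titration point from a series
#'
#' @param series A [titration_series()].
#' @param ratio A ratio present in the series.
#' @return The [peak_list()] at that ratio.
#' @export
series_point <- function(series, ratio) {
  stopifnot(inherits(series, "titration_series"))
  i <- which(abs(series$ratios - ratio) < 1e-12)
  if (length(i) != 1L) {
    stop("ratio ", ratio, " not in series; available: ",
         paste(series$ratios, collapse = ", "))
  }
  series$points[[i]]
}

#' Construct an ESI-MS centroid spectrum
#'
#' @param peptide_total Total peptide concentration (uM).
#' @param metal_total Total Ag+ concentration (uM).
#' @param peaks data.frame with columns `mz` (Th, > 0) and `area` (>= 0).
#' @return An object of class `ms_spectrum`.
#' @export
ms_spectrum <- function(peptide_total, metal_total, peaks) {
  stopifnot(is.numeric(peptide_total), peptide_total >= 0,
            is.numeric(metal_total), metal_total >= 0)
  peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)
  if (nrow(peaks) > 0L) {
    stopifnot(all(c("mz", "area") %in% names(peaks)))
    if (any(!is.finite(peaks$mz)) || any(peaks$mz <= 0)) {
      stop("m/z values must be finite and > 0")
    }
    if (any(!is.finite(peaks$area)) || any(peaks$area < 0)) {
      stop("peak areas must be finite and >= 0")
    }
    peaks <- peaks[order(peaks$mz), c("mz", "area")]
    rownames(peaks) <- NULL
  } else {
    peaks <- data.frame(mz = numeric(0), area = numeric(0))
  }
  structure(
    list(peptide_total = peptide_total, metal_total = metal_total,
         peaks = peaks),
    class = "ms_spectrum"
  )
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf(
    "<ms_spectrum> %d centroids; peptide %.4g uM, Ag+ %.4g uM\n",
    nrow(x$peaks), x$peptide_total, x$metal_total
  ))
  invisible(x)
}

#' Read an ESI-MS centroid list from a two-column CSV/TSV
#'
#' Expected header: `mz,area`. An empty file yields an empty spectrum with a
#' warning.
#'
#' @inheritParams ms_spectrum
#' @param path File path.
#' @return An [ms_spectrum()].
#' @export
read_ms_spectrum <- function(path, peptide_total, metal_total) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- .parse_delim_table(path, c("mz", "area"))
  if (is.null(tab) || nrow(tab) == 0L) {
    warning("empty centroid list: ", path)
    return(ms_spectrum(peptide_total, metal_total,
                       data.frame(mz = numeric(0), area = numeric(0))))
  }
  peaks <- data.frame(
    mz = as.numeric(tab$mz),
    area = as.numeric(tab$area)
  )
  if (any(is.na(peaks$mz)) || any(is.na(peaks$area))) {
    stop("malformed numeric value in centroid list ", path)
  }
  ms_spectrum(peptide_total, metal_total, peaks)
}

#' Write an ESI-MS centroid spectrum to CSV
#'
#' @param x An [ms_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ms_spectrum <- function(x, path) {
  stopifnot(inherits(x, "ms_spectrum"))
  utils::write.table(
    data.frame(mz = formatC(x$peaks$mz, digits = 6, format = "f"),
               area = formatC(x$peaks$area, digits = 6, format = "g")),
    path, sep = ",", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
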