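# Peptide sequences and molecular masses.

# Average and monoisotopic residue masses (Da) for the 20 standard amino
# acids, residue = amino acid minus one water. IUPAC 2021 atomic weights.
.AA_MASS_AVG <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, V = 99.1326,  W = 186.2132, Y = 163.1760
)
.AA_MASS_MONO <- c(
  A = 71.03711,  R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146,  H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203,  T = 101.04768, V = 99.06841,  W = 186.07931, Y = 163.06333
)
.MASS_WATER <- c(average = 18.01528, monoisotopic = 18.010565)

# Cation masses used for adduct m/z arithmetic (electron mass subtracted).
.MASS_PROTON <- 1.007276
.MASS_AG_CATION <- c(average = 107.86767, monoisotopic = 106.90454)

.AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", E = "Glu",
  Q = "Gln", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", V = "Val",
  W = "Trp", Y = "Tyr"
)

#' Construct a peptide sequence
#'
#' A validated one-letter peptide sequence with a numbering offset that maps
#' peptide-local residue indices (1-based) onto positions in the parent
#' protein. For the SilE model peptide SP2 (residues 77-92 of SilE) the
#' offset is 77, so local residue 11 is reported as "87His".
#'
#' @param one_letter Character scalar of standard one-letter amino-acid codes.
#' @param numbering_offset Integer >= 1; parent-protein index of residue 1.
#' @return An object of class `peptide_sequence`.
#' @examples
#' sp2 <- peptide_sequence("ADAHQKMVESHQRMMG", numbering_offset = 77)
#' residue_label(sp2, 11) # "87His"
#' @export
peptide_sequence <- function(one_letter, numbering_offset = 1L) {
  stopifnot(is.character(one_letter), length(one_letter) == 1L)
  one_letter <- toupper(trimws(one_letter))
  if (nchar(one_letter) == 0L) {
    stop("peptide sequence must be non-empty")
  }
  res <- strsplit(one_letter, "")[[1]]
  bad <- setdiff(unique(res), names(.AA_MASS_AVG))
  if (length(bad) > 0L) {
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  }
  numbering_offset <- as.integer(numbering_offset)
  if (is.na(numbering_offset) || numbering_offset < 1L) {
    stop("numbering_offset must be an integer >= 1")
  }
  structure(
    list(one_letter = one_letter, numbering_offset = numbering_offset),
    class = "peptide_sequence"
  )
}

#' @export
print.peptide_sequence <- function(x, ...) {
  n <- nchar(x$one_letter)
  cat(sprintf(
    "<peptide_sequence> %s (%d residues, protein numbering %d-%d)\n",
    x$one_letter, n, x$numbering_offset, x$numbering_offset + n - 1L
  ))
  invisible(x)
}

#' @export
length.peptide_sequence <- function(x) nchar(x$one_letter)

#' Residue letters of a peptide sequence
#'
#' @param sequence A [peptide_sequence()].
#' @return Character vector of one-letter codes, one per residue.
#' @export
residue_letters <- function(sequence) {
  stopifnot(inherits(sequence, "peptide_sequence"))
  strsplit(sequence$one_letter, "")[[1]]
}

#' Parent-protein residue label
#'
#' Formats a peptide-local residue index in the field's "87His" style using
#' the sequence's numbering offset.
#'
#' @param sequence A [peptide_sequence()].
#' @param residue_index Integer vector of peptide-local (1-based) indices.
#' @return Character vector of labels such as `"90Met"`.
#' @export
residue_label <- function(sequence, residue_index) {
  res <- residue_letters(sequence)
  if (any(residue_index < 1L | residue_index > length(res))) {
    stop("residue_index out of range for this sequence")
  }
  paste0(
    sequence$numbering_offset + residue_index - 1L,
    .AA_THREE[res[residue_index]]
  )
}

#' Peptide molecular mass
#'
#' Sum of residue masses plus one water, in average or monoisotopic mass
#' convention. The average convention reproduces the vendor-style molecular
#' weights quoted for synthetic peptides (e.g. 1856.12 Da for the 16-residue
#' SilE fragment SP2).
#'
#' @param sequence A [peptide_sequence()] or a plain one-letter string.
#' @param mode `"average"` (default) or `"monoisotopic"`.
#' @return Mass in Da.
#' @examples
#' peptide_mass("ADAHQKMVESHQRMMG") # ~1856.12
#' @export
peptide_mass <- function(sequence, mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  if (is.character(sequence)) sequence <- peptide_sequence(sequence)
  stopifnot(inherits(sequence, "peptide_sequence"))
  res <- residue_letters(sequence)
  tab <- if (mode == "average") .AA_MASS_AVG else .AA_MASS_MONO
  sum(tab[res]) + .MASS_WATER[[mode]]
}
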