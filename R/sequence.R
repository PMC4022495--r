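# Sequence-derived thermostability metrics: charged/polar composition,
# theoretical average molecular mass, oligomer stoichiometry from a measured
# (light-scattering) mass, and the hinge-motif proline check.

CHARGED_AA <- c("K", "R", "E", "D")
POLAR_AA <- c("N", "S", "Q", "T")

# average (not monoisotopic) residue masses, Da
RESIDUE_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
                  C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
                  H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
                  M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
                  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

#' Create a sequence record
#'
#' @param one_letter amino-acid sequence (20-letter alphabet).
#' @param first_number author number of the first residue (e.g. 20 for a
#'   construct spanning residues 20-246).
#' @return object of class `sequence_record`.
#' @export
sequence_record <- function(one_letter, first_number = 1L) {
  one_letter <- toupper(gsub("[[:space:]]", "", one_letter))
  validate_sequence(one_letter)
  structure(list(one_letter = one_letter,
                 first_number = as.integer(first_number)),
            class = "sequence_record")
}

validate_sequence <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  if (length(ch) < 1) stop("empty sequence")
  bad <- which(!(ch %in% names(RESIDUE_MASS)))
  if (length(bad))
    stop(sprintf("invalid residue '%s' at position %d", ch[bad[1]], bad[1]))
  invisible(ch)
}

as_seq_chars <- function(seq) {
  if (inherits(seq, "sequence_record")) seq <- seq$one_letter
  validate_sequence(toupper(gsub("[[:space:]]", "", seq)))
}

#' Charged/polar amino-acid composition
#'
#' Charged = Lys, Arg, Glu, Asp; polar = Asn, Ser, Gln, Thr; His belongs to
#' neither class.  Percentages are reported to 1 decimal.
#'
#' @param seq a string or [sequence_record].
#' @return list of class `composition_report`: `pct_charged`, `pct_polar`,
#'   `n_charged`, `n_polar`, `length`, `counts` (per amino acid).
#' @export
composition <- function(seq) {
  ch <- as_seq_chars(seq)
  n <- length(ch)
  n_charged <- sum(ch %in% CHARGED_AA)
  n_polar <- sum(ch %in% POLAR_AA)
  structure(list(pct_charged = round(100 * n_charged / n, 1),
                 pct_polar = round(100 * n_polar / n, 1),
                 n_charged = n_charged, n_polar = n_polar, length = n,
                 counts = table(factor(ch, names(RESIDUE_MASS)))),
            class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat(sprintf("composition: %d residues; charged %.1f%% (%d), polar %.1f%% (%d)\n",
              x$length, x$pct_charged, x$n_charged, x$pct_polar, x$n_polar))
  invisible(x)
}

#' Theoretical average molecular mass of a peptide
#'
#' Sum of average residue masses plus one water (18.015 Da), reported to the
#' nearest Dalton by default.
#'
#' @param seq a string or [sequence_record].
#' @param digits rounding (default 0; use NA for the unrounded value).
#' @return mass in Daltons.
#' @export
theoretical_mass <- function(seq, digits = 0) {
  ch <- as_seq_chars(seq)
  m <- sum(RESIDUE_MASS[ch]) + WATER_MASS
  if (is.na(digits)) m else round(m, digits)
}

#' Oligomer stoichiometry from a measured mass
#'
#' @param measured_mass_kda weight-average molar mass from e.g. SEC-MALS, kDa.
#' @param monomer_mass_da theoretical monomer mass, Da.
#' @param flag_tolerance |ratio - n| above which the assignment is flagged
#'   ambiguous (default 0.15).
#' @return list: `ratio`, `n` (nearest integer), `ambiguous` (logical).
#' @export
stoichiometry <- function(measured_mass_kda, monomer_mass_da,
                          flag_tolerance = 0.15) {
  if (measured_mass_kda <= 0 || monomer_mass_da <= 0)
    stop("masses must be positive")
  ratio <- measured_mass_kda / (monomer_mass_da / 1000)
  n <- round(ratio)
  list(ratio = ratio, n = as.integer(n),
       ambiguous = abs(ratio - n) > flag_tolerance)
}

#' Extract a hinge motif and check for proline
#'
#' @param seq a [sequence_record] (or string, then `first_number` applies).
#' @param hinge_range length-2 vector (start, end) in author numbering.
#' @param first_number used when `seq` is a bare string.
#' @return list: `sequence` (the extracted motif), `contains_proline`,
#'   `range`.
#' @export
hinge_motif_check <- function(seq, hinge_range, first_number = 1L) {
  if (!inherits(seq, "sequence_record"))
    seq <- sequence_record(seq, first_number)
  ch <- as_seq_chars(seq)
  idx <- hinge_range - seq$first_number + 1L
  if (idx[1] < 1 || idx[2] > length(ch) || idx[1] > idx[2])
    stop(sprintf("hinge range %d-%d outside sequence numbering %d-%d",
                 hinge_range[1], hinge_range[2], seq$first_number,
                 seq$first_number + length(ch) - 1L))
  motif <- paste(ch[idx[1]:idx[2]], collapse = "")
  list(sequence = motif, contains_proline = grepl("P", motif),
       range = hinge_range)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @param first_number author number of the first residue of each record.
#' @return named list of [sequence_record]s.
#' @export
read_fasta_sequences <- function(path, first_number = 1L) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA headers in ", path)
  ends <- c(hdr[-1] - 1L, length(lines))
  out <- list()
  for (k in seq_along(hdr)) {
    nm <- sub("^>\\s*", "", lines[hdr[k]])
    nm <- strsplit(nm, "\\s+")[[1]][1]
    body <- paste(lines[(hdr[k] + 1L):ends[k]], collapse = "")
    out[[nm]] <- sequence_record(body, first_number)
  }
  out
}
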