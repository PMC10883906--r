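#' Normalize and validate a 23-mer guide or target sequence
#'
#' Sequences are uppercased and RNA uracil is mapped to thymine before
#' validation, so sgRNA sequences written in the RNA alphabet are accepted.
#' The only admissible characters after normalization are A, C, G, T and the
#' wildcard N; the length must be exactly 23 (20-nt spacer + NGG PAM context).
#'
#' @param seq character scalar
#' @return normalized character scalar
#' @export
#' @examples
#' normalize_sequence("acguacguacguacguacgungg")
normalize_sequence <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    abort_cf("sequence must be a single non-NA character string", "InvalidAlphabet")
  }
  s <- chartr("u", "U", toupper(seq))
  s <- chartr("U", "T", s)
  if (nchar(s) != GUIDE_LENGTH) {
    abort_cf(
      sprintf("sequence length %d, expected %d", nchar(s), GUIDE_LENGTH),
      "InvalidSequenceLength"
    )
  }
  bad <- setdiff(strsplit(s, "")[[1]], c(BASES, "N"))
  if (length(bad)) {
    abort_cf(
      sprintf("invalid character(s) in sequence: %s", paste(unique(bad), collapse = ", ")),
      "InvalidAlphabet"
    )
  }
  s
}

seq_chars <- function(seq) strsplit(normalize_sequence(seq), "")[[1]]

#' Mismatching positions of an sgRNA/target pair
#'
#' Positions are 1-based with position 1 at the PAM-distal end and positions
#' 21-23 forming the PAM. A position where either sequence carries the
#' wildcard N never counts as a mismatch (the wildcard carries no base
#' identity).
#'
#' @param sgrna,dna 23-mer sequences (normalized internally)
#' @return increasing integer vector of mismatching positions
#' @export
#' @examples
#' mismatch_positions("GACGTACGTACGTACGTACGNGG", "GACGTACGTACGTACGAACGTGG")
mismatch_positions <- function(sgrna, dna) {
  a <- seq_chars(sgrna)
  b <- seq_chars(dna)
  which(a != b & a != "N" & b != "N")
}

# warn (once per call) when position 21 carries a concrete base on the sgRNA
# side; benchmark-style data keeps the NGG wildcard there
check_wildcard_pos <- function(sgrna_chars) {
  sgrna_chars[WILDCARD_POS] != "N"
}
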