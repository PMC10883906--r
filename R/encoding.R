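#' One-hot encode a single 23-mer
#'
#' Column order is (A, T, C, G) -- the same order used as the precedence
#' ranking for the 5-channel direction bit. The wildcard N encodes as an
#' all-zero row: it carries no base identity.
#'
#' @param seq 23-mer sequence
#' @return 23 x 4 binary matrix, columns named A, T, C, G
#' @export
#' @examples
#' one_hot("GACGTACGTACGTACGTACGNGG")[1:3, ]
one_hot <- function(seq) {
  chars <- seq_chars(seq)
  m <- matrix(0, nrow = GUIDE_LENGTH, ncol = 4L, dimnames = list(NULL, BASES))
  idx <- match(chars, BASES)
  keep <- !is.na(idx)
  m[cbind(which(keep), idx[keep])] <- 1
  m
}

#' Encode an sgRNA/target-DNA pair as a superposed one-hot matrix
#'
#' The two sequences are one-hot encoded independently and superposed with a
#' logical OR (`channels = 4`). With `channels = 5` a direction channel is
#' appended: at a mismatched position it is 1 exactly when the
#' higher-precedence base (precedence A > T > C > G) originates from the
#' target DNA, and it is 0 at every matched position.
#'
#' A matched position thus has row sum 1 over the base channels, a mismatched
#' position row sum 2, and a position involving the wildcard N contributes
#' only the concrete base (or nothing when both are N).
#'
#' @param sgrna,dna 23-mer sequences
#' @param channels 4 (superposed) or 5 (superposed + direction)
#' @return 23 x channels binary matrix
#' @export
#' @examples
#' encode_pair("GACGTACGTACGTACGTACGNGG", "GACGTACGTACGTACGAACGTGG", channels = 5)
encode_pair <- function(sgrna, dna, channels = 4L) {
  channels <- as.integer(channels)
  if (!channels %in% c(4L, 5L)) abort_cf("channels must be 4 or 5", "InvalidChannels")
  a <- one_hot(sgrna)
  b <- one_hot(dna)
  m <- pmax(a, b)
  if (channels == 5L) {
    ca <- seq_chars(sgrna)
    cb <- seq_chars(dna)
    mm <- ca != cb & ca != "N" & cb != "N"
    # precedence rank: smaller index in (A, T, C, G) outranks
    dir <- as.numeric(mm & match(cb, BASES) < match(ca, BASES))
    dir[is.na(dir)] <- 0
    m <- cbind(m, direction = dir)
  }
  m
}

#' Encode a dataset of pairs into a batch array
#'
#' @param data data.frame with columns `sgrna` and `dna` (and optionally
#'   `label`)
#' @param channels 4 or 5
#' @return numeric array of dim `c(nrow(data), 23, channels)`
#' @export
encode_dataset <- function(data, channels = 4L) {
  stopifnot(is.data.frame(data), all(c("sgrna", "dna") %in% names(data)))
  n <- nrow(data)
  x <- array(0, dim = c(n, GUIDE_LENGTH, as.integer(channels)))
  for (i in seq_len(n)) {
    x[i, , ] <- encode_pair(data$sgrna[i], data$dna[i], channels = channels)
  }
  x
}

# decode the (sgRNA base, DNA base) at each position into feature labels used
# by the attribution reports, e.g. "AA:match", "TG:mismatch", "NA:wildcard"
pair_feature_labels <- function(sgrna, dna) {
  a <- seq_chars(sgrna)
  b <- seq_chars(dna)
  tag <- ifelse(
    a == "N" | b == "N", "wildcard",
    ifelse(a == b, "match", "mismatch")
  )
  paste0(a, b, ":", tag)
}
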