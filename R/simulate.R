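#' Planted positional mismatch rule
#'
#' A deterministic label function over a guide/target pair: the pair is
#' labeled an off-target (1) exactly when the number of mismatches inside
#' each region stays within its tolerance. The defaults encode the
#' biological prior the interpretation stage is expected to recover --
#' mismatches in the PAM-proximal seed (16-20) or a broken PAM abolish
#' cleavage, while distal and seed-core mismatches are tolerated.
#'
#' Position 21 is the PAM wildcard and never counts as a mismatch, so a PAM
#' tolerance of 0 means positions 22-23 (the GG of NGG) must be intact.
#'
#' @param distal,core,proximal,pam maximum tolerated mismatch counts per
#'   region (regions per [guide_regions()])
#' @param regions region partition, see [guide_regions()]
#' @return object of class `planted_rule`: a predicate over (sgrna, dna)
#' @export
#' @examples
#' rule <- planted_rule()
#' rule("GACGTACGTACGTACGTACGNGG", "GACGTACGTACGTACGTACGTGG") # intact -> 1
planted_rule <- function(distal = Inf, core = Inf, proximal = 0L, pam = 0L,
                         regions = guide_regions()) {
  tol <- c(distal = distal, core = core, proximal = proximal, pam = pam)
  stopifnot(all(tol >= 0))
  fn <- function(sgrna, dna) {
    mm <- mismatch_positions(sgrna, dna)
    ok <- vapply(
      names(regions),
      function(r) sum(mm %in% regions[[r]]) <= tol[[r]],
      logical(1)
    )
    as.integer(all(ok))
  }
  structure(fn, class = c("planted_rule", "function"),
            tolerances = tol, regions = regions)
}

#' Substitute bases at given positions
#'
#' Each listed position receives a uniformly drawn base different from the
#' original one; every other position is untouched. Position 21 (the PAM
#' wildcard N) may not be mutated.
#'
#' @param seq 23-mer sequence
#' @param positions distinct 1-based positions in 1..23, excluding 21
#' @return mutated sequence
#' @export
inject_mismatches <- function(seq, positions) {
  chars <- seq_chars(seq)
  positions <- as.integer(positions)
  if (anyDuplicated(positions) || any(positions < 1L | positions > GUIDE_LENGTH)) {
    abort_cf("positions must be distinct and within 1..23", "WildcardPositionError")
  }
  if (WILDCARD_POS %in% positions) {
    abort_cf("position 21 is the PAM wildcard and cannot be mutated", "WildcardPositionError")
  }
  for (p in positions) {
    chars[p] <- sample(setdiff(BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

random_sgrna <- function() {
  paste0(paste(sample(BASES, 20L, replace = TRUE), collapse = ""), "NGG")
}

# one candidate target for an sgRNA: concrete base at the wildcard position,
# then a mismatch count drawn from `weights` over 0..max_mismatches and that
# many substitutions at distinct non-wildcard positions
sample_target <- function(sgrna, max_mismatches = 6L,
                          weights = rep(1, max_mismatches + 1L)) {
  chars <- seq_chars(sgrna)
  chars[WILDCARD_POS] <- sample(BASES, 1L)
  dna <- paste(chars, collapse = "")
  k <- sample.int(max_mismatches + 1L, 1L, prob = weights) - 1L
  if (k > 0L) {
    pos <- sample(setdiff(seq_len(GUIDE_LENGTH), WILDCARD_POS), k)
    dna <- inject_mismatches(dna, pos)
  }
  dna
}

#' Simulation configuration
#'
#' Defaults mirror the shape of the DeepCRISPR-style benchmark this package
#' targets: 23-mers with an NGG PAM, at most six substitution mismatches and
#' a 1:230 positive:negative imbalance.
#'
#' @param n_records total number of pairs to emit
#' @param imbalance_ratio negatives per positive (>= 1); default 230
#' @param max_mismatches maximum substitutions per pair; default 6
#' @param rule a [planted_rule()] labeling function
#' @param noise label-flip probability in `[0, 0.5)`; default 0
#' @param mismatch_weights sampling weights for mismatch counts
#'   `0..max_mismatches` (normalized internally); default uniform
#' @param seed integer seed; the same config + seed yields a byte-identical
#'   dataset
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_records = 2310L, imbalance_ratio = 230,
                       max_mismatches = 6L, rule = planted_rule(),
                       noise = 0, mismatch_weights = NULL, seed = 1L) {
  stopifnot(n_records >= 2L, imbalance_ratio >= 1,
            max_mismatches >= 0L, max_mismatches <= 6L,
            noise >= 0, noise < 0.5)
  if (is.null(mismatch_weights)) mismatch_weights <- rep(1, max_mismatches + 1L)
  stopifnot(length(mismatch_weights) == max_mismatches + 1L, all(mismatch_weights >= 0))
  structure(
    list(n_records = as.integer(n_records), imbalance_ratio = imbalance_ratio,
         max_mismatches = as.integer(max_mismatches), rule = rule,
         noise = noise, mismatch_weights = mismatch_weights,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Generate a synthetic labeled dataset
#'
#' Emits `n_records` sgRNA/target pairs whose class ratio matches
#' `imbalance_ratio` exactly (positives = `round(n / (ratio + 1))`), labels
#' assigned by the planted rule before optional label-flip noise. Pairs are
#' produced by rejection: candidates are drawn via [sample_target()]-style
#' substitution until each class quota is filled.
#'
#' @param cfg a [sim_config()]
#' @return data.frame (`sgrna`, `dna`, `label`) with attribute
#'   `provenance = "synthetic"`
#' @export
#' @examples
#' d <- generate_dataset(sim_config(n_records = 231, imbalance_ratio = 230, seed = 7))
#' table(d$label)
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_pos <- max(1L, round(cfg$n_records / (cfg$imbalance_ratio + 1)))
  n_neg <- cfg$n_records - n_pos
  with_seed(cfg$seed, {
    sg <- character(cfg$n_records)
    dn <- character(cfg$n_records)
    lab <- integer(cfg$n_records)
    need <- c(`1` = n_pos, `0` = n_neg)
    got <- 0L
    tries <- 0L
    max_tries <- 2000L * cfg$n_records
    while (got < cfg$n_records) {
      tries <- tries + 1L
      if (tries > max_tries) {
        abort_cf(
          sprintf(
            "could not reach the %s:1 class ratio under the planted rule (still need %d positives, %d negatives)",
            cfg$imbalance_ratio, need[["1"]], need[["0"]]
          ),
          "GenerationError"
        )
      }
      s <- random_sgrna()
      d <- sample_target(s, cfg$max_mismatches, cfg$mismatch_weights)
      y <- cfg$rule(s, d)
      key <- as.character(y)
      if (need[[key]] > 0L) {
        got <- got + 1L
        need[[key]] <- need[[key]] - 1L
        sg[got] <- s
        dn[got] <- d
        lab[got] <- y
      }
    }
    if (cfg$noise > 0) {
      flip <- runif(cfg$n_records) < cfg$noise
      lab[flip] <- 1L - lab[flip]
    }
    perm <- sample.int(cfg$n_records)
    out <- data.frame(
      sgrna = sg[perm], dna = dn[perm], label = lab[perm],
      stringsAsFactors = FALSE
    )
    attr(out, "provenance") <- "synthetic"
    out
  })
}
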