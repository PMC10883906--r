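#' Hyperparameter search space
#'
#' The discrete grids over which model selection runs: batch size 32-256
#' (doubling), epochs 10-100 (step 10), 1 or 2 recurrent layers,
#' uni/bidirectional, dropout 0.10-0.50 (step 0.05), recurrent hidden size
#' 32-512 (doubling), 0-6 fully-connected hidden layers and a 1-5 ladder of
#' learning rates from 1e-5 to 0.5. The admissible number of hidden layers
#' additionally depends on the hidden size (see [max_hidden_layers()]).
#'
#' @return named list of grids, class `search_space`
#' @export
#' @examples
#' default_search_space()
default_search_space <- function() {
  structure(list(
    batch_size         = c(32L, 64L, 128L, 256L),
    epochs             = seq(10L, 100L, by = 10L),
    n_recurrent_layers = c(1L, 2L),
    bidirectional      = c(FALSE, TRUE),
    dropout_p          = seq(0.10, 0.50, by = 0.05),
    hidden_size        = c(32L, 64L, 128L, 256L, 512L),
    n_hidden_layers    = 0:6,
    learning_rate      = c(1e-5, 5e-5, 1e-4, 5e-4, 1e-3, 5e-3, 1e-2, 5e-2, 1e-1, 5e-1)
  ), class = "search_space")
}

#' Maximum admissible number of fully-connected hidden layers
#'
#' Hidden-layer widths halve starting at `hidden_size`; every width must stay
#' >= 2 and the grid caps the count at 6, so the admissible maximum is
#' `min(6, floor(log2(hidden_size)))`.
#'
#' @param hidden_size recurrent hidden size
#' @return integer in 0..6
#' @export
#' @examples
#' max_hidden_layers(512) # 6
#' max_hidden_layers(32)  # 5
max_hidden_layers <- function(hidden_size) {
  stopifnot(hidden_size >= 1)
  pmin(6L, as.integer(floor(log2(hidden_size))))
}

#' Size of the hyperparameter search space
#'
#' Product of the grid cardinalities. With `include_hidden_layers = FALSE`
#' the hidden-layer gene is left out (the configuration count the search is
#' usually quoted at: 72 000 for the default grids); with `TRUE` the
#' hidden-size-dependent admissible counts are summed before multiplying the
#' remaining grids.
#'
#' @param space a [default_search_space()]-style list
#' @param include_hidden_layers logical
#' @return integer count
#' @export
#' @examples
#' search_space_size(default_search_space()) # 72000
search_space_size <- function(space = default_search_space(),
                              include_hidden_layers = FALSE) {
  others <- setdiff(names(space), c("n_hidden_layers", "hidden_size"))
  base <- prod(vapply(space[others], length, integer(1)))
  if (include_hidden_layers) {
    per_h <- vapply(
      space$hidden_size,
      function(h) sum(space$n_hidden_layers <= max_hidden_layers(h)),
      integer(1)
    )
    base * sum(per_h)
  } else {
    base * length(space$hidden_size)
  }
}

#' Construct and validate a hyperparameter genome
#'
#' A genome is one value per tunable gene plus the recurrent cell type, which
#' is fixed per search run (crossover across cell types is not meaningful).
#'
#' @param cell_type "RNN", "LSTM" or "GRU"
#' @param batch_size,epochs,n_recurrent_layers,bidirectional,dropout_p,hidden_size,n_hidden_layers,learning_rate
#'   gene values, each a member of its grid
#' @param space search space to validate against
#' @return named list of class `hp_genome`
#' @export
#' @examples
#' genome(cell_type = "LSTM", hidden_size = 512, n_hidden_layers = 2,
#'        bidirectional = TRUE, dropout_p = 0.4, batch_size = 64,
#'        epochs = 50, learning_rate = 1e-4)
genome <- function(cell_type, batch_size = 64L, epochs = 10L,
                   n_recurrent_layers = 1L, bidirectional = FALSE,
                   dropout_p = 0.1, hidden_size = 64L, n_hidden_layers = 0L,
                   learning_rate = 1e-3, space = default_search_space()) {
  g <- structure(list(
    cell_type = toupper(cell_type),
    batch_size = as.integer(batch_size),
    epochs = as.integer(epochs),
    n_recurrent_layers = as.integer(n_recurrent_layers),
    bidirectional = as.logical(bidirectional),
    dropout_p = as.numeric(dropout_p),
    hidden_size = as.integer(hidden_size),
    n_hidden_layers = as.integer(n_hidden_layers),
    learning_rate = as.numeric(learning_rate)
  ), class = "hp_genome")
  validate_genome(g, space)
  g
}

#' @rdname genome
#' @param g an `hp_genome`
#' @export
validate_genome <- function(g, space = default_search_space()) {
  if (!g$cell_type %in% c("RNN", "LSTM", "GRU")) {
    abort_cf(sprintf("invalid gene cell_type: %s", g$cell_type), "InvalidGenome")
  }
  near <- function(v, grid) any(abs(grid - v) < 1e-12)
  for (gene in names(space)) {
    if (gene == "n_hidden_layers") next
    if (!near(g[[gene]], space[[gene]])) {
      abort_cf(sprintf("invalid gene %s: %s", gene, g[[gene]]), "InvalidGenome")
    }
  }
  cap <- max_hidden_layers(g$hidden_size)
  if (!g$n_hidden_layers %in% space$n_hidden_layers || g$n_hidden_layers > cap) {
    abort_cf(
      sprintf("invalid gene n_hidden_layers: %d (cap %d for hidden size %d)",
              g$n_hidden_layers, cap, g$hidden_size),
      "InvalidGenome"
    )
  }
  invisible(g)
}

# clamp the hidden-layer count to its hidden-size-dependent cap (used after
# crossover/mutation, which treat genes independently)
clamp_genome <- function(g) {
  cap <- max_hidden_layers(g$hidden_size)
  if (g$n_hidden_layers > cap) g$n_hidden_layers <- cap
  g
}

#' Draw a uniformly random genome
#'
#' Each gene is drawn uniformly from its grid; the hidden-layer count is
#' drawn uniformly from the admissible `0..max_hidden_layers(hidden_size)`.
#'
#' @inheritParams genome
#' @param space search space
#' @return `hp_genome`
#' @export
random_genome <- function(cell_type, space = default_search_space()) {
  pick <- function(grid) grid[[sample.int(length(grid), 1L)]]
  h <- pick(space$hidden_size)
  nh_grid <- space$n_hidden_layers[space$n_hidden_layers <= max_hidden_layers(h)]
  genome(
    cell_type = cell_type,
    batch_size = pick(space$batch_size),
    epochs = pick(space$epochs),
    n_recurrent_layers = pick(space$n_recurrent_layers),
    bidirectional = pick(space$bidirectional),
    dropout_p = pick(space$dropout_p),
    hidden_size = h,
    n_hidden_layers = pick(nh_grid),
    learning_rate = pick(space$learning_rate),
    space = space
  )
}

genome_key <- function(g) {
  paste(vapply(unclass(g), function(v) format(v, digits = 15), character(1)),
        collapse = "|")
}

#' @export
print.hp_genome <- function(x, ...) {
  cat("<hyperparameter genome>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
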