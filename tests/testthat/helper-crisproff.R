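# shared fixtures and independent oracles, all built in code

ns <- asNamespace("crisproff")

tiny_genome <- function(cell = "LSTM", ...) {
  args <- list(cell_type = cell, hidden_size = 32L, batch_size = 32L,
               epochs = 10L, n_recurrent_layers = 1L, bidirectional = FALSE,
               dropout_p = 0.1, n_hidden_layers = 1L, learning_rate = 1e-3)
  do.call(genome, utils::modifyList(args, list(...)))
}

# deterministic 23-mers for encoding tests
seq_a <- "GACGTACGTACGTACGTACGNGG"

random_pair_df <- function(n, seed = 1, channels_n = FALSE) {
  set.seed(seed)
  sg <- replicate(n, paste0(paste(sample(c("A", "C", "G", "T"), 20, TRUE),
                                  collapse = ""), "NGG"))
  dna <- vapply(sg, function(s) {
    ch <- strsplit(s, "")[[1]]
    ch[21] <- sample(c("A", "C", "G", "T"), 1)
    k <- sample(0:6, 1)
    if (k > 0) {
      for (p in sample(setdiff(1:23, 21), k)) {
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      }
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  data.frame(sgrna = sg, dna = dna,
             label = sample(0:1, n, TRUE), stringsAsFactors = FALSE)
}

# memoized small model trained on the planted rule; shared across the
# interpretation and IO tests so the suite trains it once
.toy_cache <- new.env(parent = emptyenv())

make_trained_toy <- function(seed = 13) {
  key <- as.character(seed)
  if (is.null(.toy_cache[[key]])) {
    d <- generate_dataset(sim_config(n_records = 400, imbalance_ratio = 3,
                                     seed = seed))
    g <- tiny_genome("GRU", epochs = 10, batch_size = 32, learning_rate = 5e-3,
                     n_hidden_layers = 2)
    m <- train_model(build_model(g, seed = seed), d, seed = seed)
    .toy_cache[[key]] <- list(model = m, data = d)
  }
  .toy_cache[[key]]
}

# brute-force average precision: enumerate every distinct threshold,
# compute precision/recall, sum step areas (independent of the package path)
ap_bruteforce <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  prev_rec <- 0
  ap <- 0
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / P
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# high-resolution numerical path integral of the target logit gradient,
# oracle for integrated-gradients completeness (independent of backprop:
# finite differences of the forward pass only)
ig_path_oracle <- function(model, x, baseline, fine_steps = 2000) {
  tc <- 2L
  alphas <- (seq_len(fine_steps) - 0.5) / fine_steps
  f <- function(xx) {
    ns$model_forward(model, array(xx, c(1, dim(xx))))$logits[1, tc]
  }
  total <- 0
  d <- x - baseline
  for (a in alphas) {
    xa <- baseline + a * d
    # directional derivative along d via central difference
    h <- 1e-4
    total <- total + (f(xa + h * d) - f(xa - h * d)) / (2 * h)
  }
  total / fine_steps # equals f(x) - f(baseline) in the limit
}

expect_rel_equal <- function(a, b, tol = 1e-6) {
  expect_lt(abs(a - b) / max(1e-8, abs(a) + abs(b)), tol)
}
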