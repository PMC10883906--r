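# A small 3-gene sub-space (64 genomes) with a deterministic fitness whose
# unique optimum is known by exhaustive enumeration; used to verify the
# whole evolutionary loop end to end.
small_space <- function() {
  sp <- default_search_space()
  sp$batch_size <- 32L
  sp$epochs <- 10L
  sp$n_recurrent_layers <- 1L
  sp$bidirectional <- FALSE
  sp$dropout_p <- c(0.10, 0.20, 0.30, 0.40)
  sp$hidden_size <- c(32L, 64L, 128L, 256L)
  sp$n_hidden_layers <- 0L
  sp$learning_rate <- c(1e-4, 5e-4, 1e-3, 5e-3)
  sp
}

synthetic_fitness <- function(g) {
  # smooth deterministic landscape, unique optimum at
  # (dropout 0.2, hidden 128, lr 1e-3)
  1 - (abs(g$dropout_p - 0.2) + abs(log2(g$hidden_size) - 7) / 10 +
         abs(log10(g$learning_rate) + 3) / 10)
}

enumerate_genomes <- function(sp, cell = "RNN") {
  out <- list()
  for (dp in sp$dropout_p) for (h in sp$hidden_size) for (lr in sp$learning_rate) {
    out[[length(out) + 1L]] <- genome(
      cell, batch_size = 32, epochs = 10, n_recurrent_layers = 1,
      bidirectional = FALSE, dropout_p = dp, hidden_size = h,
      n_hidden_layers = 0, learning_rate = lr
    )
  }
  out
}

test_that("population initialization is uniform, seeded and grid-respecting", {
  cfg <- ga_config(seed = 5)
  pop <- init_population("LSTM", config = cfg)
  expect_length(pop, 20L)
  expect_identical(pop, init_population("LSTM", config = cfg))
  for (g in pop) expect_silent(validate_genome(g))
  # frequency check: 10000 draws of the batch-size gene (4-value grid)
  pop_big <- init_population("RNN", config = ga_config(population_size = 10000,
                                                       seed = 8))
  freq <- table(vapply(pop_big, `[[`, integer(1), "batch_size")) / 10000
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(freq - 0.25) < 3 * se))
})

test_that("tournament selection prefers the fit and matches its closed form", {
  expect_error(tournament_select(c(0.5), 2), class = "SelectionError")
  set.seed(1)
  expect_equal(tournament_select(c(0.1, 0.9), 2), 2L)
  # tournament = population -> always the global best
  f <- c(0.3, 0.8, 0.1, 0.5)
  for (i in 1:10) expect_equal(tournament_select(f, 4), 2L)
  # empirical win rate of fitness rank r in 2-way tournaments without
  # replacement: 2(n-r)/(n(n-1))
  fit <- seq(0.1, 1.0, by = 0.1)
  n <- 10
  draws <- 20000
  set.seed(2)
  wins <- table(factor(replicate(draws, tournament_select(fit, 2)), levels = 1:10))
  r <- n + 1 - rank(fit) # rank 1 = best
  p_theory <- 2 * (n - r) / (n * (n - 1))
  se <- sqrt(p_theory * (1 - p_theory) / draws)
  expect_true(all(abs(wins / draws - p_theory) <= 3 * se + 1e-9))
})

test_that("crossover swaps per gene at the configured probability", {
  a <- tiny_genome("LSTM", hidden_size = 32, learning_rate = 1e-3)
  b <- tiny_genome("LSTM", hidden_size = 512, learning_rate = 1e-5,
                   dropout_p = 0.5, batch_size = 256)
  set.seed(3)
  k0 <- crossover(a, b, prob = 0)
  expect_equal(k0[[1]], a)
  expect_equal(k0[[2]], b)
  k1 <- crossover(a, b, prob = 1)
  expect_equal(k1[[1]][names(k1[[1]]) != "n_hidden_layers"],
               b[names(b) != "n_hidden_layers"])
  expect_equal(k1[[2]], a)
  same <- crossover(a, a, prob = 0.7)
  expect_equal(same[[1]], a)
  expect_error(crossover(a, tiny_genome("GRU")), class = "CrossoverError")
  # empirical per-gene swap rate over 10000 trials
  set.seed(4)
  hits <- 0L
  for (i in 1:10000) {
    k <- crossover(a, b, prob = 0.3)
    hits <- hits + (k[[1]]$batch_size == b$batch_size)
  }
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(hits / 10000 - 0.3), 3 * se)
})

test_that("mutation redraws genes uniformly at the configured probability", {
  g <- tiny_genome("RNN")
  set.seed(5)
  expect_equal(mutate(g, prob = 0), g)
  # singleton grids leave the genome unchanged
  sp1 <- lapply(default_search_space(), function(v) v[1])
  sp1$hidden_size <- g$hidden_size; sp1$batch_size <- g$batch_size
  sp1$epochs <- g$epochs; sp1$n_recurrent_layers <- g$n_recurrent_layers
  sp1$bidirectional <- g$bidirectional; sp1$dropout_p <- g$dropout_p
  sp1$n_hidden_layers <- g$n_hidden_layers; sp1$learning_rate <- g$learning_rate
  expect_equal(mutate(g, space = structure(sp1, class = "search_space"), prob = 1), g)
  # prob 1 on the 4-value batch grid: change rate ~ 0.75 (uniform redraw
  # includes the current value)
  set.seed(6)
  changed <- 0L
  for (i in 1:10000) {
    changed <- changed + (mutate(g, prob = 1)$batch_size != g$batch_size)
  }
  se <- sqrt(0.75 * 0.25 / 10000)
  expect_lt(abs(changed / 10000 - 0.75), 3 * se)
  # mutation always yields a valid genome (hidden-layer cap re-clamped)
  g2 <- tiny_genome("RNN", hidden_size = 512, n_hidden_layers = 6)
  set.seed(7)
  for (i in 1:200) expect_silent(validate_genome(mutate(g2, prob = 1)))
})

test_that("the elitist GA finds the exhaustively-verified optimum", {
  sp <- small_space()
  all_g <- enumerate_genomes(sp)
  expect_length(all_g, 64L)
  best_exhaustive <- max(vapply(all_g, synthetic_fitness, numeric(1)))
  res <- evolve("RNN", synthetic_fitness, space = sp,
                config = ga_config(seed = 31))
  expect_equal(res$best$fitness, best_exhaustive, tolerance = 1e-12)
  expect_equal(res$best$genome$dropout_p, 0.2)
  expect_equal(res$best$genome$hidden_size, 128L)
  expect_equal(res$best$genome$learning_rate, 1e-3)
})

test_that("elitist best-so-far is non-decreasing and population size constant", {
  sp <- small_space()
  for (seed in 1:20) {
    res <- evolve("RNN", synthetic_fitness, space = sp,
                  config = ga_config(n_generations = 8, seed = seed))
    h <- res$history
    expect_true(all(table(h$generation) == 20L))
    gen_max <- tapply(h$fitness, h$generation, max)
    expect_true(all(diff(gen_max) >= -1e-12))
  }
})

test_that("evolve replays exactly under its seed and survives callback failure", {
  sp <- small_space()
  cfg <- ga_config(n_generations = 4, seed = 17)
  r1 <- evolve("RNN", synthetic_fitness, space = sp, config = cfg)
  r2 <- evolve("RNN", synthetic_fitness, space = sp, config = cfg)
  expect_identical(r1$history, r2$history)
  # n_generations = 0: best of the initial population only
  r0 <- evolve("RNN", synthetic_fitness, space = sp,
               config = ga_config(n_generations = 0, seed = 17))
  expect_equal(unique(r0$history$generation), 0)
  expect_equal(r0$best$fitness, max(r0$history$fitness))
  # a failing callback records fitness 0 with the error note, run continues
  flaky <- function(g) {
    if (g$hidden_size == 64L) stop("boom")
    synthetic_fitness(g)
  }
  rf <- evolve("RNN", flaky, space = sp, config = cfg)
  failed <- rf$history[rf$history$note != "", ]
  expect_gt(nrow(failed), 0)
  expect_true(all(failed$fitness == 0))
  expect_match(failed$note[1], "boom")
})

test_that("history records parentage and mutation masks", {
  sp <- small_space()
  res <- evolve("RNN", synthetic_fitness, space = sp,
                config = ga_config(n_generations = 3, seed = 12))
  h <- res$history
  expect_true(all(h$parents[h$generation == 0] == ""))
  later <- h[h$generation > 0, ]
  expect_true(all(grepl("^elite:[0-9]+$|^[0-9]+,[0-9]+$", later$parents)))
  # elites are carried unchanged: 4 per generation after the first
  expect_true(all(tapply(grepl("^elite:", later$parents), later$generation, sum) == 4))
  # recorded mutation masks name real genes
  genes <- unlist(strsplit(later$mutated[later$mutated != ""], ";"))
  expect_true(all(genes %in% crisproff:::GENE_NAMES))
})

test_that("every genome the GA produces stays inside the search space", {
  sp <- small_space()
  res <- evolve("LSTM", function(g) g$dropout_p, space = sp,
                config = ga_config(n_generations = 6, seed = 9))
  for (js in res$history$genome) {
    g <- do.call(genome, c(jsonlite::fromJSON(js), list(space = sp)))
    expect_s3_class(g, "hp_genome")
  }
})
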