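#' Genetic-algorithm configuration
#'
#' Defaults are the study configuration: population 20, 4 elites, 2-way
#' tournaments, per-gene crossover probability 0.3, per-gene mutation
#' probability 0.2, 20 generations.
#'
#' @param population_size,elite_count,tournament_size,n_generations positive
#'   integers; `elite_count < population_size`
#' @param crossover_prob,mutation_prob per-gene probabilities in `[0, 1]`
#' @param variant "elitist" (elites carried unchanged into the next
#'   generation) or "plain" (whole population replaced)
#' @param seed integer seed
#' @return list of class `ga_config`
#' @export
ga_config <- function(population_size = 20L, elite_count = 4L,
                      tournament_size = 2L, crossover_prob = 0.3,
                      mutation_prob = 0.2, n_generations = 20L,
                      variant = c("elitist", "plain"), seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(population_size >= 2L, elite_count >= 0L,
            elite_count < population_size, tournament_size >= 1L,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1, n_generations >= 0L)
  structure(list(
    population_size = as.integer(population_size),
    elite_count = as.integer(elite_count),
    tournament_size = as.integer(tournament_size),
    crossover_prob = crossover_prob, mutation_prob = mutation_prob,
    n_generations = as.integer(n_generations), variant = variant,
    seed = as.integer(seed)
  ), class = "ga_config")
}

GENE_NAMES <- c("batch_size", "epochs", "n_recurrent_layers", "bidirectional",
                "dropout_p", "hidden_size", "n_hidden_layers", "learning_rate")

#' Initial random population
#'
#' @param cell_type recurrent cell type, fixed for the whole run
#' @param space search space
#' @param config a [ga_config()]
#' @return list of `hp_genome`s of length `population_size`
#' @export
init_population <- function(cell_type, space = default_search_space(),
                            config = ga_config()) {
  with_seed(derive_seed(config$seed, "init"), {
    lapply(seq_len(config$population_size), function(i) random_genome(cell_type, space))
  })
}

#' Tournament selection
#'
#' Draws `tournament_size` individuals uniformly without replacement and
#' returns the index of the fittest; ties break toward the earlier
#' population index. Uses the current RNG stream.
#'
#' @param fitness numeric fitness vector (all evaluated)
#' @param tournament_size number of entrants
#' @return integer index of the winner
#' @export
tournament_select <- function(fitness, tournament_size = 2L) {
  n <- length(fitness)
  if (n < tournament_size) {
    abort_cf("population smaller than tournament size", "SelectionError")
  }
  entrants <- sort(sample.int(n, tournament_size))
  entrants[which.max(fitness[entrants])]
}

#' Per-gene uniform crossover
#'
#' For each gene independently, with probability `prob` the two parents'
#' values are swapped. Offspring are re-clamped to the hidden-layer cap.
#' Parents must share a cell type: recombining across recurrent cell types
#' is not meaningful.
#'
#' @param a,b parent genomes
#' @param prob per-gene swap probability
#' @return list of two offspring genomes
#' @export
crossover <- function(a, b, prob = 0.3) {
  if (a$cell_type != b$cell_type) {
    abort_cf("cannot cross genomes of different cell types", "CrossoverError")
  }
  swap <- runif(length(GENE_NAMES)) < prob
  for (k in which(swap)) {
    gene <- GENE_NAMES[k]
    tmp <- a[[gene]]
    a[[gene]] <- b[[gene]]
    b[[gene]] <- tmp
  }
  list(clamp_genome(a), clamp_genome(b))
}

#' Per-gene uniform mutation
#'
#' Each gene is independently replaced, with probability `prob`, by a
#' uniform draw from its full grid (the current value may be redrawn, so the
#' realized change rate is `prob * (1 - 1/grid size)`). The result is
#' re-clamped to the hidden-layer cap.
#'
#' @param g genome
#' @param space search space
#' @param prob per-gene mutation probability
#' @return mutated genome
#' @export
mutate <- function(g, space = default_search_space(), prob = 0.2) {
  hit <- runif(length(GENE_NAMES)) < prob
  for (k in which(hit)) {
    gene <- GENE_NAMES[k]
    grid <- space[[gene]]
    g[[gene]] <- grid[[sample.int(length(grid), 1L)]]
  }
  clamp_genome(g)
}

#' Evolve hyperparameters with a (plain or elitist) genetic algorithm
#'
#' Runs the search over the discrete space, maximizing the fitness callback
#' (validation AUPRC when wrapping [train_model()] + [evaluate()], or any
#' deterministic landscape for testing). The elitist variant copies the
#' `elite_count` fittest individuals unchanged into the next generation and
#' fills the remaining slots with tournament-selected, crossed-over and
#' mutated offspring; the plain variant replaces the whole population.
#' Identical genomes reuse a cached fitness (training is the bottleneck);
#' a callback error records fitness 0 with a note and the run continues.
#' Returns the best individual over all generations.
#'
#' @param cell_type "RNN", "LSTM" or "GRU"
#' @param fitness_fn function(genome) -> numeric in `[0, 1]`
#' @param space search space
#' @param config a [ga_config()]
#' @return list with `best` (list: genome, fitness), `history` (data.frame:
#'   generation, individual, genome JSON, fitness, parents -- `"i,j"`
#'   tournament winners, `"elite:k"` for carried elites, `""` for the random
#'   initial population -- mutated gene names, and the error note) and
#'   `config`
#' @export
#' @examples
#' fit <- function(g) 1 - abs(log2(g$hidden_size) - 8) / 8 # peak at 256
#' res <- evolve("GRU", fit, config = ga_config(n_generations = 3, seed = 2))
#' res$best$fitness
evolve <- function(cell_type, fitness_fn, space = default_search_space(),
                   config = ga_config()) {
  cache <- new.env(parent = emptyenv())
  score <- function(g) {
    key <- genome_key(g)
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- tryCatch(
      list(fit = as.numeric(fitness_fn(g)), note = ""),
      error = function(e) list(fit = 0, note = conditionMessage(e))
    )
    cache[[key]] <- res
    res
  }
  pop <- init_population(cell_type, space, config)
  parentage <- rep("", config$population_size)       # "i,j" indices, "" = random init
  mutmask <- rep("", config$population_size)         # ";"-joined mutated genes
  history <- NULL
  best <- list(genome = NULL, fitness = -Inf)
  with_seed(derive_seed(config$seed, "evolve"), {
    for (gen in 0:config$n_generations) {
      evals <- lapply(pop, score)
      fitness <- vapply(evals, `[[`, numeric(1), "fit")
      history <- rbind(history, data.frame(
        generation = gen,
        individual = seq_along(pop),
        genome = vapply(pop, function(g) {
          jsonlite::toJSON(unclass(g), auto_unbox = TRUE)
        }, character(1)),
        fitness = fitness,
        parents = parentage,
        mutated = mutmask,
        note = vapply(evals, `[[`, character(1), "note"),
        stringsAsFactors = FALSE
      ))
      gen_best <- which.max(fitness)
      if (fitness[gen_best] > best$fitness) {
        best <- list(genome = pop[[gen_best]], fitness = fitness[gen_best])
      }
      if (gen == config$n_generations) break
      n_offspring <- config$population_size -
        if (config$variant == "elitist") config$elite_count else 0L
      offspring <- list()
      off_parents <- character(0)
      off_mut <- character(0)
      while (length(offspring) < n_offspring) {
        i <- tournament_select(fitness, config$tournament_size)
        j <- tournament_select(fitness, config$tournament_size)
        kids <- crossover(pop[[i]], pop[[j]], config$crossover_prob)
        kids <- lapply(kids, function(k) {
          mk <- mutate(k, space = space, prob = config$mutation_prob)
          changed <- GENE_NAMES[vapply(GENE_NAMES, function(nm) {
            !identical(k[[nm]], mk[[nm]])
          }, logical(1))]
          attr(mk, "mutated") <- paste(changed, collapse = ";")
          mk
        })
        offspring <- c(offspring, kids)
        off_parents <- c(off_parents, rep(paste(i, j, sep = ","), 2L))
        off_mut <- c(off_mut,
                     vapply(kids, function(k) attr(k, "mutated"), character(1)))
      }
      keep_n <- seq_len(n_offspring)
      offspring <- lapply(offspring[keep_n], function(k) {
        attr(k, "mutated") <- NULL
        k
      })
      if (config$variant == "elitist") {
        elite_idx <- order(-fitness, seq_along(fitness))[seq_len(config$elite_count)]
        pop <- c(pop[elite_idx], offspring)
        parentage <- c(paste0("elite:", elite_idx), off_parents[keep_n])
        mutmask <- c(rep("", config$elite_count), off_mut[keep_n])
      } else {
        pop <- offspring
        parentage <- off_parents[keep_n]
        mutmask <- off_mut[keep_n]
      }
    }
  })
  list(best = best, history = history, config = config)
}

#' Fitness callback wrapping model training
#'
#' Builds the standard GA objective: build a model from the genome, train it
#' on `train` with balanced bootstrap batches, score validation AUPRC.
#'
#' @param train,validation labeled data.frames
#' @param channels 4 or 5
#' @param seed integer seed shared across genome evaluations
#' @return function(genome) -> validation AUPRC
#' @export
training_fitness <- function(train, validation, channels = 4L, seed = 1L) {
  force(train); force(validation); force(channels); force(seed)
  function(g) {
    m <- build_model(g, channels = channels, seed = derive_seed(seed, "weights"))
    m <- train_model(m, train, seed = derive_seed(seed, "train"))
    sc <- predict(m, validation, type = "prob")[, 2L]
    average_precision(sc, validation$label)
  }
}
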