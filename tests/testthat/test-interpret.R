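test_that("a zero path (input == baseline) yields all-zero attributions", {
  m <- build_model(tiny_genome("RNN"), seed = 1)
  x <- encode_pair(seq_a, seq_a)
  ig <- integrated_gradients(m, x, baseline = x, steps = 8)
  expect_equal(max(abs(ig$attributions)), 0)
  expect_equal(ig$score_gap, 0)
})

test_that("linear scorers are attributed exactly weight * (input - baseline)", {
  set.seed(2)
  w <- matrix(rnorm(23 * 4), 23, 4)
  grad_fn <- function(xb) {
    g <- array(0, dim(xb))
    for (k in seq_len(dim(xb)[1])) g[k, , ] <- w
    g
  }
  x <- encode_pair(seq_a, "GACGTACGTACGTACGAACGTGG")
  baseline <- matrix(0, 23, 4)
  for (steps in c(1L, 7L, 50L)) {
    attr <- ns$ig_core(grad_fn, x, baseline, steps)
    expect_equal(attr, w * x, tolerance = 1e-15)
  }
})

test_that("baseline shape mismatches raise a typed error", {
  m <- build_model(tiny_genome("RNN"), seed = 1)
  expect_error(
    integrated_gradients(m, encode_pair(seq_a, seq_a), baseline = matrix(0, 23, 5)),
    class = "BaselineShapeError"
  )
  expect_error(
    integrated_gradients(m, matrix(0, 23, 5)),
    class = "BaselineShapeError"
  )
})

test_that("completeness holds against a fine-grid path-integral oracle", {
  toy <- make_trained_toy()
  x <- encode_pair(toy$data$sgrna[1], toy$data$dna[1])
  baseline <- matrix(0, 23, 4)
  ig <- integrated_gradients(toy$model, x, steps = 256)
  tol <- max(1e-3, 10 / 256 * abs(ig$score_gap))
  expect_lt(abs(ig$residual), tol)
  # independent oracle: numerical directional-derivative quadrature of the
  # forward pass only
  oracle <- ig_path_oracle(toy$model, x, baseline, fine_steps = 600)
  expect_equal(sum(ig$attributions), oracle, tolerance = 1e-2)
  expect_equal(oracle, ig$score_gap, tolerance = 1e-2)
  # residual shrinks as steps grow
  r8 <- abs(integrated_gradients(toy$model, x, steps = 8)$residual)
  r128 <- abs(integrated_gradients(toy$model, x, steps = 128)$residual)
  expect_lt(r128, r8 + 1e-12)
})

test_that("feature importance normalizes, aggregates and ranks correctly", {
  toy <- make_trained_toy()
  sub <- toy$data[1:30, ]
  tab <- feature_importance(toy$model, sub, steps = 16)
  # one row per observed (position, feature) combination
  expect_true(all(tab$position %in% 1:23))
  expect_true(all(grepl(":(match|mismatch|wildcard)$", tab$feature)))
  # ranks are permutations
  for (a in c("positive", "negative", "all")) {
    expect_setequal(tab[[paste0("rank_", a)]], seq_len(nrow(tab)))
  }
  # aggregation conservation: the all-sample mean is the presence-weighted
  # mean of the class-conditional aggregates
  mp <- ifelse(is.na(tab$mean_positive), 0, tab$mean_positive)
  mn <- ifelse(is.na(tab$mean_negative), 0, tab$mean_negative)
  expect_equal(tab$mean_all,
               (tab$n_positive * mp + tab$n_negative * mn) / tab$n_all,
               tolerance = 1e-12)
  # single sample: the table is that sample's normalized attribution
  one <- feature_importance(toy$model, toy$data[7, , drop = FALSE], steps = 16)
  x1 <- encode_pair(toy$data$sgrna[7], toy$data$dna[7])
  ig1 <- integrated_gradients(toy$model, x1, steps = 16)
  scores1 <- ns$normalized_position_scores(ig1$attributions, x1)
  expect_equal(sort(one$mean_all), sort(scores1[one$position]), tolerance = 1e-12)
  expect_equal(sum(abs(scores1)), 1, tolerance = 1e-12)
  # top-n extraction returns n rows in rank order
  top <- top_features(tab, 15, "positive")
  expect_equal(nrow(top), 15L)
  expect_equal(top$rank_positive, 1:15)
})

test_that("region summaries partition positions and sign simple tables correctly", {
  # hand-built table: positive scores only in the proximal region
  tab <- data.frame(
    position = 1:23,
    feature = rep("AA:match", 23),
    mean_positive = ifelse(1:23 %in% 16:20, 0.5, 0),
    n_positive = 1L,
    mean_negative = 0, n_negative = 1L,
    mean_all = ifelse(1:23 %in% 16:20, 0.25, 0), n_all = 2L
  )
  tab$rank_positive <- rank(-tab$mean_positive, ties.method = "first")
  tab$rank_negative <- rank(-tab$mean_negative, ties.method = "first")
  tab$rank_all <- rank(-tab$mean_all, ties.method = "first")
  rs <- region_summary(tab)
  expect_equal(rs$region, c("distal", "core", "proximal", "pam"))
  expect_equal(rs$mean_positive, c(0, 0, 0.5, 0))
  # all-equal scores give all-equal regional means
  tab$mean_positive <- 0.3
  rs2 <- region_summary(tab)
  expect_equal(rs2$mean_positive, rep(0.3, 4))
  # positively correlated mismatch features are counted per region
  tab$feature[18] <- "TG:mismatch"
  tab$mean_positive <- ifelse(1:23 == 18, 0.2, -0.1)
  rs3 <- region_summary(tab)
  expect_equal(rs3$pos_corr_mismatch_positive, c(0L, 0L, 1L, 0L))
})

test_that("layer attribution ranks neurons and collapses to completeness for one unit", {
  toy <- make_trained_toy()
  sub <- toy$data[1:10, ]
  nr <- layer_attribution(toy$model, sub, steps = 32)
  expect_setequal(unique(nr$layer), 1:2)
  expect_equal(nrow(nr), sum(toy$model$spec$fc_widths))
  expect_setequal(nr$rank_all, seq_len(nrow(nr)))
  # single-hidden-unit surgery: all influence flows through one neuron, so
  # its conductance approximates the score gap
  m <- build_model(tiny_genome("RNN", n_hidden_layers = 1), seed = 4)
  m$spec$fc_widths <- 1L
  set.seed(5)
  m$params[["fc1.W"]] <- matrix(abs(rnorm(m$spec$handoff_width, sd = 0.5)), ncol = 1)
  m$params[["fc1.b"]] <- 0.3
  m$params[["out.W"]] <- matrix(c(-0.8, 0.9), 1, 2)
  m$params[["out.b"]] <- c(0, 0)
  d1 <- random_pair_df(3, seed = 6)
  la <- layer_attribution(m, d1, steps = 400)
  x <- encode_dataset(d1)
  gaps <- vapply(1:3, function(i) {
    ends <- array(0, c(2, 23, 4))
    ends[1, , ] <- x[i, , ]
    lg <- ns$model_forward(m, ends)$logits[, 2]
    lg[1] - lg[2]
  }, numeric(1))
  expect_equal(la$mean_all[la$layer == 1], mean(gaps), tolerance = 1e-3)
  # models without hidden layers cannot be layer-attributed
  m0 <- build_model(tiny_genome("RNN", n_hidden_layers = 0), seed = 1)
  expect_error(layer_attribution(m0, d1), class = "NoHiddenLayers")
})

test_that("activation heatmaps are post-ReLU and consistent with column means", {
  toy <- make_trained_toy()
  sub <- toy$data[1:12, ]
  hm <- activation_heatmap(toy$model, sub, layer_index = 1)
  expect_equal(dim(hm), c(12L, toy$model$spec$fc_widths[1]))
  expect_true(all(hm >= 0))
  # dead neuron: zero incoming weights and bias -> all-zero column
  m <- toy$model
  m$params[["fc1.W"]][, 3] <- 0
  m$params[["fc1.b"]][3] <- 0
  hm2 <- activation_heatmap(m, sub, 1)
  expect_equal(unname(hm2[, 3]), rep(0, 12))
  # column means equal the per-neuron mean activation
  expect_equal(unname(colMeans(hm)[5]), mean(hm[, 5]))
})
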