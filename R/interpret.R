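#' Integrated gradients for one encoded pair
#'
#' Attribution of each input entry as `(x - x') * mean_k dF/dx` evaluated on
#' the straight path from the baseline `x'` to the input `x` at midpoint
#' Riemann nodes `alpha = (k - 1/2)/steps`, where `F` is the target-class
#' logit. The default baseline is the all-zero matrix: the natural
#' "no sequence information" reference for a binary encoding. The
#' completeness residual `sum(attr) - (F(x) - F(x'))` is always reported and
#' shrinks as `steps` grows.
#'
#' @param model a `crisproff_model`
#' @param x encoded 23 x channels matrix (see [encode_pair()])
#' @param baseline same shape as `x`; default all zeros
#' @param steps number of Riemann nodes (>= 1)
#' @param target "positive" or "negative" class logit
#' @return list of class `attribution`: `attributions` (23 x C),
#'   `score_gap`, `residual`, `steps`, `target`
#' @export
integrated_gradients <- function(model, x, baseline = NULL, steps = 50L,
                                 target = c("positive", "negative")) {
  target <- match.arg(target)
  tc <- if (target == "positive") 2L else 1L
  steps <- as.integer(steps)
  stopifnot(steps >= 1L)
  x <- as.matrix(x)
  if (is.null(baseline)) baseline <- matrix(0, nrow(x), ncol(x))
  baseline <- as.matrix(baseline)
  if (!all(dim(x) == c(GUIDE_LENGTH, model$spec$channels)) ||
      !all(dim(baseline) == dim(x))) {
    abort_cf("input/baseline must be 23 x channels matrices matching the model",
             "BaselineShapeError")
  }
  grad_fn <- function(xb) {
    fwd <- model_forward(model, xb, keep_cache = TRUE)
    dlogits <- matrix(0, dim(xb)[1], model$spec$n_classes)
    dlogits[, tc] <- 1
    model_backward(model, fwd$cache, dlogits)$dx
  }
  attr <- ig_core(grad_fn, x, baseline, steps)
  ends <- array(0, c(2, GUIDE_LENGTH, ncol(x)))
  ends[1, , ] <- x
  ends[2, , ] <- baseline
  lg <- model_forward(model, ends)$logits[, tc]
  gap <- lg[1] - lg[2]
  structure(list(
    attributions = attr, score_gap = gap, residual = sum(attr) - gap,
    steps = steps, target = target
  ), class = "attribution")
}

# Midpoint-rule path integration shared by all attribution entry points:
# attr = (x - x') * mean_k grad(x' + alpha_k (x - x')), alpha_k = (k-1/2)/steps.
# grad_fn maps a [steps, 23, C] batch to the per-row gradient of the target
# score with respect to the input.
ig_core <- function(grad_fn, x, baseline, steps) {
  diffm <- x - baseline
  alphas <- (seq_len(steps) - 0.5) / steps
  xb <- array(0, c(steps, nrow(x), ncol(x)))
  for (k in seq_len(steps)) xb[k, , ] <- baseline + alphas[k] * diffm
  g <- grad_fn(xb)
  diffm * apply(g, c(2, 3), mean)
}

# per-sample L1 normalization over the features present (nonzero input
# entries), then a per-position score = sum over that position's active
# channels -- the unit the feature-importance table aggregates
normalized_position_scores <- function(attr, x) {
  present <- x != 0
  denom <- sum(abs(attr[present]))
  norm <- matrix(0, nrow(x), ncol(x))
  if (denom > 0) norm[present] <- attr[present] / denom
  rowSums(norm)
}

#' Positional feature importance from integrated gradients
#'
#' For every sample: attribute with respect to the target class, L1-normalize
#' over the features present in that sample, collapse each position's active
#' channels into one score, and label it by the decoded (sgRNA base, DNA
#' base) with a match/mismatch/wildcard tag. Scores are then averaged per
#' feature across positive-labeled, negative-labeled and all samples, and
#' ranked per aggregate by the magnitude of the mean (a strongly negatively
#' correlated feature is a top contributor too; the signed mean carries the
#' direction). A feature's aggregate mean uses the
#' samples in which that feature occurs.
#'
#' @param model a trained `crisproff_model`
#' @param data labeled data.frame (`sgrna`, `dna`, `label`)
#' @param steps integration steps per sample
#' @param target attribution target class
#' @return data.frame of class `feature_importance_table` with columns
#'   position, feature, mean/n per aggregate and rank per aggregate,
#'   ordered by `rank_all`
#' @export
feature_importance <- function(model, data, steps = 50L,
                               target = c("positive", "negative")) {
  target <- match.arg(target)
  stopifnot(nrow(data) > 0L, all(c("sgrna", "dna", "label") %in% names(data)))
  x <- encode_dataset(data, channels = model$spec$channels)
  n <- nrow(data)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    xi <- matrix(x[i, , ], GUIDE_LENGTH, model$spec$channels)
    ig <- integrated_gradients(model, xi, steps = steps, target = target)
    rows[[i]] <- data.frame(
      position = seq_len(GUIDE_LENGTH),
      feature = pair_feature_labels(data$sgrna[i], data$dna[i]),
      score = normalized_position_scores(ig$attributions, xi),
      label = as.integer(data$label[i]),
      stringsAsFactors = FALSE
    )
  }
  long <- do.call(rbind, rows)
  key <- paste(long$position, long$feature, sep = "\r")
  agg <- function(sub) {
    out <- rep(NA_real_, length(unique(key)))
    names(out) <- unique(key)
    if (nrow(sub)) {
      m <- tapply(sub$score, paste(sub$position, sub$feature, sep = "\r"), mean)
      out[names(m)] <- m
    }
    out
  }
  cnt <- function(sub) {
    out <- integer(length(unique(key)))
    names(out) <- unique(key)
    if (nrow(sub)) {
      m <- table(paste(sub$position, sub$feature, sep = "\r"))
      out[names(m)] <- as.integer(m)
    }
    out
  }
  uk <- unique(key)
  pos_sub <- long[long$label == 1L, ]
  neg_sub <- long[long$label == 0L, ]
  tab <- data.frame(
    position = as.integer(sub("\r.*", "", uk)),
    feature = sub(".*\r", "", uk),
    mean_positive = agg(pos_sub)[uk],
    n_positive = cnt(pos_sub)[uk],
    mean_negative = agg(neg_sub)[uk],
    n_negative = cnt(neg_sub)[uk],
    mean_all = agg(long)[uk],
    n_all = cnt(long)[uk],
    stringsAsFactors = FALSE, row.names = NULL
  )
  # "top contributing" is ranked by attribution magnitude: strongly
  # negatively correlated features are top-ranked alongside positive ones,
  # with the signed mean carrying the correlation direction
  for (a in c("positive", "negative", "all")) {
    m <- tab[[paste0("mean_", a)]]
    tab[[paste0("rank_", a)]] <- rank(-replace(abs(m), is.na(m), -Inf),
                                      ties.method = "first")
  }
  tab <- tab[order(tab$rank_all), ]
  row.names(tab) <- NULL
  attr(tab, "target") <- target
  attr(tab, "steps") <- steps
  class(tab) <- c("feature_importance_table", "data.frame")
  tab
}

#' Top-ranked features of an importance table
#'
#' @param table a [feature_importance()] result
#' @param n number of rows
#' @param aggregate which ranking to use
#' @return the `n` top rows in rank order
#' @export
top_features <- function(table, n = 15L, aggregate = c("all", "positive", "negative")) {
  aggregate <- match.arg(aggregate)
  o <- order(table[[paste0("rank_", aggregate)]])
  out <- table[o[seq_len(min(n, nrow(table)))], ]
  row.names(out) <- NULL
  out
}

#' Region-level attribution summary
#'
#' Signed mean attribution per sgRNA region (PAM-distal 1-10, seed-core
#' 11-15, PAM-proximal 16-20, PAM 21-23 by default) for each aggregate
#' class, plus the count of positively correlated mismatch features per
#' region and aggregate.
#'
#' @param table a [feature_importance()] result
#' @param regions region partition, see [guide_regions()]
#' @return data.frame of class `region_summary`, one row per region
#' @export
region_summary <- function(table, regions = guide_regions()) {
  stopifnot(setequal(unlist(regions), seq_len(GUIDE_LENGTH)))
  out <- data.frame(
    region = names(regions),
    positions = vapply(regions, function(p) paste(range(p), collapse = "-"),
                       character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  is_mm <- grepl(":mismatch$", table$feature)
  for (a in c("positive", "negative", "all")) {
    m <- table[[paste0("mean_", a)]]
    out[[paste0("mean_", a)]] <- vapply(regions, function(p) {
      v <- m[table$position %in% p]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    out[[paste0("pos_corr_mismatch_", a)]] <- vapply(regions, function(p) {
      sum(table$position %in% p & is_mm & !is.na(m) & m > 0)
    }, integer(1))
  }
  class(out) <- c("region_summary", "data.frame")
  out
}

#' Neuron-level attribution of fully-connected hidden layers
#'
#' Layer-conductance-style attribution: along the same straight input path
#' used by [integrated_gradients()], each hidden neuron (post-ReLU activation
#' `a_n`) receives `sum_k g_n(alpha_k) * (a_n(alpha_k) - a_n(alpha_{k-1}))`
#' where `g_n` is the gradient of the target-class logit with respect to the
#' activation. Per-neuron scores are averaged across positive, negative and
#' all samples and ranked per aggregate by magnitude of the mean.
#'
#' @param model a trained `crisproff_model`
#' @param data labeled data.frame
#' @param layer_index one 1-based hidden-layer index, or `NULL` for all
#' @param steps path resolution
#' @param target attribution target class
#' @return data.frame of class `neuron_ranking`: layer, neuron, mean and
#'   rank per aggregate
#' @export
layer_attribution <- function(model, data, layer_index = NULL, steps = 50L,
                              target = c("positive", "negative")) {
  target <- match.arg(target)
  tc <- if (target == "positive") 2L else 1L
  nh <- length(model$spec$fc_widths)
  if (nh == 0L) {
    abort_cf("model has no fully-connected hidden layers", "NoHiddenLayers")
  }
  layers <- layer_index %||% seq_len(nh)
  stopifnot(all(layers >= 1L), all(layers <= nh))
  x <- encode_dataset(data, channels = model$spec$channels)
  n <- nrow(data)
  labels <- as.integer(data$label)
  alphas <- (0:steps) / steps
  sums <- lapply(layers, function(j) matrix(0, n, model$spec$fc_widths[j]))
  names(sums) <- as.character(layers)
  for (i in seq_len(n)) {
    xi <- matrix(x[i, , ], GUIDE_LENGTH, model$spec$channels)
    xb <- array(0, c(steps + 1L, GUIDE_LENGTH, ncol(xi)))
    for (k in seq_along(alphas)) xb[k, , ] <- alphas[k] * xi
    fwd <- model_forward(model, xb, keep_cache = TRUE)
    dlogits <- matrix(0, steps + 1L, model$spec$n_classes)
    dlogits[, tc] <- 1
    bwd <- model_backward(model, fwd$cache, dlogits, want_fc_act_grads = TRUE)
    for (j in layers) {
      acts <- fwd$cache$fc[[j]]$act           # (steps+1) x width
      g <- bwd$fc_act_grads[[j]]
      da <- acts[-1L, , drop = FALSE] - acts[-(steps + 1L), , drop = FALSE]
      sums[[as.character(j)]][i, ] <- colSums(g[-1L, , drop = FALSE] * da)
    }
  }
  res <- lapply(layers, function(j) {
    s <- sums[[as.character(j)]]
    data.frame(
      layer = j, neuron = seq_len(ncol(s)),
      mean_positive = if (any(labels == 1L)) {
        colMeans(s[labels == 1L, , drop = FALSE])
      } else NA_real_,
      mean_negative = if (any(labels == 0L)) {
        colMeans(s[labels == 0L, , drop = FALSE])
      } else NA_real_,
      mean_all = colMeans(s),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  for (a in c("positive", "negative", "all")) {
    m <- out[[paste0("mean_", a)]]
    out[[paste0("rank_", a)]] <- rank(-replace(abs(m), is.na(m), -Inf),
                                      ties.method = "first")
  }
  out <- out[order(out$rank_all), ]
  row.names(out) <- NULL
  attr(out, "target") <- target
  attr(out, "steps") <- steps
  class(out) <- c("neuron_ranking", "data.frame")
  out
}

#' Post-ReLU activation matrix of a hidden layer
#'
#' @param model a `crisproff_model` with hidden layers
#' @param data data.frame of pairs
#' @param layer_index 1-based hidden-layer index
#' @return samples x neurons matrix of activations (all >= 0), with row and
#'   column labels
#' @export
activation_heatmap <- function(model, data, layer_index = 1L) {
  nh <- length(model$spec$fc_widths)
  if (nh == 0L) {
    abort_cf("model has no fully-connected hidden layers", "NoHiddenLayers")
  }
  stopifnot(layer_index >= 1L, layer_index <= nh)
  x <- encode_dataset(data, channels = model$spec$channels)
  n <- nrow(data)
  out <- matrix(0, n, model$spec$fc_widths[layer_index],
                dimnames = list(
                  paste0("sample", seq_len(n)),
                  paste0("neuron", seq_len(model$spec$fc_widths[layer_index]))
                ))
  start <- 1L
  while (start <= n) {
    end <- min(n, start + 511L)
    fwd <- model_forward(model, x[start:end, , , drop = FALSE], keep_cache = TRUE)
    out[start:end, ] <- fwd$cache$fc[[layer_index]]$act
    start <- end + 1L
  }
  out
}
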