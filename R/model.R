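# Generic parameterized recurrent classifier: one or two (optionally
# bidirectional) RNN/LSTM/GRU layers over the 23 x C encoded pair, the final
# time-step state(s) feeding a halving stack of fully-connected hidden layers
# (ReLU + dropout after each) and a 2-unit output layer.
#
# Implemented directly on BLAS matrix ops: sequences are 23 steps long and
# hidden sizes small, so batched R matrix products are fast, and owning the
# backward pass gives exact input gradients for integrated gradients.

GATE_MULT <- c(RNN = 1L, LSTM = 4L, GRU = 3L)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Architecture implied by a genome
#'
#' Expands a hyperparameter genome into the concrete layer structure:
#' recurrent stack (type, layers, directions, hidden size), fully-connected
#' widths (halving from `hidden_size`; every width stays >= 2) and the
#' 2-unit output.
#'
#' @param g an [genome()] object
#' @param channels input channels, 4 or 5
#' @return list of class `model_spec`
#' @export
model_spec <- function(g, channels = 4L) {
  validate_genome(g)
  channels <- as.integer(channels)
  stopifnot(channels %in% c(4L, 5L))
  ndir <- if (g$bidirectional) 2L else 1L
  widths <- if (g$n_hidden_layers > 0L) {
    as.integer(g$hidden_size / 2^(seq_len(g$n_hidden_layers) - 1L))
  } else {
    integer(0)
  }
  structure(list(
    channels = channels, cell_type = g$cell_type,
    n_recurrent_layers = g$n_recurrent_layers, ndir = ndir,
    hidden_size = g$hidden_size, dropout_p = g$dropout_p,
    fc_widths = widths, handoff_width = g$hidden_size * ndir,
    n_classes = 2L
  ), class = "model_spec")
}

#' Exact trainable-parameter count for a genome
#'
#' Closed-form count of the scalars a model built from `g` will train:
#' recurrent input/recurrent weights and bias per layer and direction (with
#' the LSTM/GRU gate multiplier), plus the dense stack and output layer.
#' Serves as an architecture regression check against the built model.
#'
#' @inheritParams model_spec
#' @return integer count
#' @export
parameter_count <- function(g, channels = 4L) {
  sp <- model_spec(g, channels)
  gm <- GATE_MULT[[sp$cell_type]]
  H <- sp$hidden_size
  total <- 0
  inp <- sp$channels
  for (l in seq_len(sp$n_recurrent_layers)) {
    total <- total + sp$ndir * (inp * gm * H + H * gm * H + gm * H)
    inp <- H * sp$ndir
  }
  prev <- sp$handoff_width
  for (w in sp$fc_widths) {
    total <- total + prev * w + w
    prev <- w
  }
  total + prev * sp$n_classes + sp$n_classes
}

init_mat <- function(nr, nc, k) matrix(runif(nr * nc, -k, k), nr, nc)

#' Build a trainable recurrent classifier from a genome
#'
#' Parameters are initialized uniformly on `(-1/sqrt(fan), 1/sqrt(fan))`
#' (recurrent: fan = hidden size; dense: fan = fan-in) under the given seed,
#' so identical genome + seed gives identical initial parameters.
#'
#' @inheritParams model_spec
#' @param seed integer initialization seed
#' @return object of class `crisproff_model`
#' @export
#' @examples
#' m <- build_model(genome("LSTM", hidden_size = 32, n_hidden_layers = 2), seed = 1)
#' m$spec$fc_widths # 32 16
build_model <- function(g, channels = 4L, seed = 1L) {
  sp <- model_spec(g, channels)
  gm <- GATE_MULT[[sp$cell_type]]
  H <- sp$hidden_size
  dirs <- c("fw", "bw")[seq_len(sp$ndir)]
  params <- list()
  with_seed(seed, {
    inp <- sp$channels
    for (l in seq_len(sp$n_recurrent_layers)) {
      k <- 1 / sqrt(H)
      for (d in dirs) {
        params[[sprintf("rec%d.%s.Wx", l, d)]] <- init_mat(inp, gm * H, k)
        params[[sprintf("rec%d.%s.Wh", l, d)]] <- init_mat(H, gm * H, k)
        params[[sprintf("rec%d.%s.b", l, d)]] <- runif(gm * H, -k, k)
      }
      inp <- H * sp$ndir
    }
    prev <- sp$handoff_width
    for (j in seq_along(sp$fc_widths)) {
      w <- sp$fc_widths[j]
      k <- 1 / sqrt(prev)
      params[[sprintf("fc%d.W", j)]] <- init_mat(prev, w, k)
      params[[sprintf("fc%d.b", j)]] <- runif(w, -k, k)
      prev <- w
    }
    k <- 1 / sqrt(prev)
    params[["out.W"]] <- init_mat(prev, sp$n_classes, k)
    params[["out.b"]] <- runif(sp$n_classes, -k, k)
  })
  structure(
    list(genome = g, spec = sp, params = params, init_seed = as.integer(seed)),
    class = "crisproff_model"
  )
}

#' @export
print.crisproff_model <- function(x, ...) {
  sp <- x$spec
  cat(sprintf(
    "<%s off-target classifier>\n  input 23 x %d | %d %s recurrent layer(s), hidden %d\n  dense widths: %s -> 2 | dropout %.2f | %s parameters\n",
    sp$cell_type, sp$channels, sp$n_recurrent_layers,
    if (sp$ndir == 2) "bidirectional" else "unidirectional",
    sp$hidden_size,
    if (length(sp$fc_widths)) paste(sp$fc_widths, collapse = ", ") else "(none)",
    sp$dropout_p, format(sum(lengths(x$params)), big.mark = ",")
  ))
  invisible(x)
}

# ---- forward ---------------------------------------------------------------

rnn_dir_forward <- function(x, Wx, Wh, b, type, reverse) {
  d <- dim(x)
  B <- d[1]; TT <- d[2]
  gm <- GATE_MULT[[type]]
  H <- ncol(Wh) / gm
  bmat <- matrix(b, B, gm * H, byrow = TRUE)
  torder <- if (reverse) rev(seq_len(TT)) else seq_len(TT)
  h <- matrix(0, B, H)
  h_seq <- array(0, c(B, TT, H))
  gates <- array(0, c(B, TT, gm * H))
  c_seq <- if (type == "LSTM") array(0, c(B, TT, H)) else NULL
  hp_n <- if (type == "GRU") array(0, c(B, TT, H)) else NULL
  cc <- matrix(0, B, H)
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
  for (t in torder) {
    xt <- tslice(x, t)
    if (type == "RNN") {
      h <- tanh(xt %*% Wx + h %*% Wh + bmat)
      gates[, t, ] <- h
    } else if (type == "LSTM") {
      z <- xt %*% Wx + h %*% Wh + bmat
      ig <- sigmoid(z[, i1, drop = FALSE])
      fg <- sigmoid(z[, i2, drop = FALSE])
      gg <- tanh(z[, i3, drop = FALSE])
      og <- sigmoid(z[, i4, drop = FALSE])
      cc <- fg * cc + ig * gg
      h <- og * tanh(cc)
      gates[, t, ] <- cbind(ig, fg, gg, og)
      c_seq[, t, ] <- cc
    } else { # GRU
      zx <- xt %*% Wx + bmat
      hp <- h %*% Wh
      rg <- sigmoid(zx[, i1, drop = FALSE] + hp[, i1, drop = FALSE])
      zg <- sigmoid(zx[, i2, drop = FALSE] + hp[, i2, drop = FALSE])
      ng <- tanh(zx[, i3, drop = FALSE] + rg * hp[, i3, drop = FALSE])
      h <- (1 - zg) * ng + zg * h
      gates[, t, ] <- cbind(rg, zg, ng)
      hp_n[, t, ] <- hp[, i3, drop = FALSE]
    }
    h_seq[, t, ] <- h
  }
  list(h_seq = h_seq, h_last = h, gates = gates, c_seq = c_seq,
       hp_n = hp_n, torder = torder)
}

# full forward pass; returns logits plus (optionally) all caches needed by
# model_backward. Dropout is active only when training = TRUE.
model_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  sp <- model$spec
  p <- model$params
  B <- dim(x)[1]
  dirs <- c("fw", "bw")[seq_len(sp$ndir)]
  keep <- keep_cache || training
  layers <- vector("list", sp$n_recurrent_layers)
  inp <- x
  for (l in seq_len(sp$n_recurrent_layers)) {
    res <- lapply(dirs, function(d) {
      rnn_dir_forward(inp,
                      p[[sprintf("rec%d.%s.Wx", l, d)]],
                      p[[sprintf("rec%d.%s.Wh", l, d)]],
                      p[[sprintf("rec%d.%s.b", l, d)]],
                      sp$cell_type, reverse = (d == "bw"))
    })
    names(res) <- dirs
    H <- sp$hidden_size
    if (sp$ndir == 2L) {
      h_seq <- array(0, c(B, GUIDE_LENGTH, 2L * H))
      h_seq[, , seq_len(H)] <- res$fw$h_seq
      h_seq[, , H + seq_len(H)] <- res$bw$h_seq
      h_last <- cbind(res$fw$h_last, res$bw$h_last)
    } else {
      h_seq <- res$fw$h_seq
      h_last <- res$fw$h_last
    }
    drop_mask <- NULL
    if (l < sp$n_recurrent_layers && training && sp$dropout_p > 0) {
      drop_mask <- array(
        (runif(length(h_seq)) >= sp$dropout_p) / (1 - sp$dropout_p),
        dim = dim(h_seq)
      )
      h_seq <- h_seq * drop_mask
    }
    layers[[l]] <- list(dirs = res, input = inp, drop_mask = drop_mask,
                        h_last = h_last)
    inp <- h_seq
  }
  handoff <- layers[[sp$n_recurrent_layers]]$h_last
  a <- handoff
  fc <- vector("list", length(sp$fc_widths))
  for (j in seq_along(sp$fc_widths)) {
    W <- p[[sprintf("fc%d.W", j)]]
    z <- a %*% W + matrix(p[[sprintf("fc%d.b", j)]], B, ncol(W), byrow = TRUE)
    act <- pmax(z, 0)
    mask <- NULL
    if (training && sp$dropout_p > 0) {
      mask <- matrix((runif(length(act)) >= sp$dropout_p) / (1 - sp$dropout_p),
                     nrow(act), ncol(act))
    }
    fc[[j]] <- list(input = a, z = z, act = act, mask = mask)
    a <- if (is.null(mask)) act else act * mask
  }
  logits <- a %*% p[["out.W"]] +
    matrix(p[["out.b"]], B, sp$n_classes, byrow = TRUE)
  out <- list(logits = logits)
  if (keep) {
    out$cache <- list(x = x, layers = layers, fc = fc, out_input = a,
                      training = training)
  }
  out
}

softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Predict off-target scores for encoded pairs
#'
#' @param object a `crisproff_model`
#' @param newdata a data.frame with `sgrna`/`dna` columns, or an already
#'   encoded `[n, 23, channels]` array
#' @param type "prob" (softmax probabilities, column 2 = positive class),
#'   "class" (0/1 by argmax) or "logits"
#' @param ... unused
#' @return matrix of probabilities/logits, or integer vector of classes
#' @export
predict.crisproff_model <- function(object, newdata,
                                    type = c("prob", "class", "logits"), ...) {
  type <- match.arg(type)
  x <- if (is.array(newdata) && length(dim(newdata)) == 3L) {
    newdata
  } else {
    encode_dataset(newdata, channels = object$spec$channels)
  }
  logits <- predict_batched(object, x)
  switch(type,
    logits = logits,
    prob = softmax(logits),
    class = as.integer(logits[, 2L] > logits[, 1L])
  )
}

# forward in chunks to bound memory on large datasets
predict_batched <- function(model, x, chunk = 512L) {
  n <- dim(x)[1]
  out <- matrix(0, n, model$spec$n_classes)
  start <- 1L
  while (start <= n) {
    end <- min(n, start + chunk - 1L)
    xi <- x[start:end, , , drop = FALSE]
    out[start:end, ] <- model_forward(model, xi)$logits
    start <- end + 1L
  }
  out
}
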