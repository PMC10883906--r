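#' Stratified train/validation/test split
#'
#' Partitions records into train/validation/test at the given fractions,
#' preserving label proportions per subset within rounding (largest-remainder
#' allocation per class, seeded shuffle of which records land where). When a
#' label column is absent or a class is missing, falls back to an
#' unstratified split with a warning.
#'
#' @param data data.frame with a `label` column (0/1)
#' @param fractions length-3 positive numeric summing to 1; default
#'   `c(0.6, 0.2, 0.2)`
#' @param seed integer seed
#' @return named list of data.frames: `train`, `validation`, `test`
#' @export
stratified_split <- function(data, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(is.data.frame(data), nrow(data) > 0L,
            length(fractions) == 3L, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8)
  strata <- if ("label" %in% names(data) && length(unique(data$label)) > 1L) {
    split(seq_len(nrow(data)), data$label)
  } else {
    if ("label" %in% names(data) && length(unique(data$label)) == 1L) {
      warning("only one class present; falling back to unstratified split",
              call. = FALSE)
    }
    list(seq_len(nrow(data)))
  }
  with_seed(seed, {
    parts <- list(integer(0), integer(0), integer(0))
    for (idx in strata) {
      idx <- sample(idx)
      n <- length(idx)
      quota <- n * fractions
      take <- floor(quota)
      rem <- quota - take
      short <- n - sum(take)
      if (short > 0L) {
        take[order(rem, decreasing = TRUE)[seq_len(short)]] <-
          take[order(rem, decreasing = TRUE)[seq_len(short)]] + 1L
      }
      bounds <- cumsum(c(0L, take))
      for (k in 1:3) {
        if (take[k] > 0L) {
          parts[[k]] <- c(parts[[k]], idx[(bounds[k] + 1L):bounds[k + 1L]])
        }
      }
    }
    list(
      train = data[sort(parts[[1]]), , drop = FALSE],
      validation = data[sort(parts[[2]]), , drop = FALSE],
      test = data[sort(parts[[3]]), , drop = FALSE]
    )
  })
}

#' Class-balanced bootstrap mini-batches
#'
#' Builds one epoch of mini-batch index sets in which the two classes are
#' equally represented: negatives (the majority class in off-target data)
#' are consumed without replacement until exhausted -- which defines the
#' epoch -- while positives are resampled with replacement. The last batch
#' holds however many negatives remain, matched by an equal number of
#' positives.
#'
#' @param labels 0/1 vector
#' @param batch_size requested batch size; odd values are rounded down to
#'   even with a message
#' @param seed integer seed
#' @return list of integer index vectors into `labels`
#' @export
balanced_batches <- function(labels, batch_size, seed = 1L) {
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  if (!length(pos) || !length(neg)) {
    abort_cf("balanced batching needs both classes present", "BalancingImpossible")
  }
  batch_size <- as.integer(batch_size)
  if (batch_size %% 2L == 1L) {
    batch_size <- batch_size - 1L
    message("batch size rounded down to even: ", batch_size)
  }
  stopifnot(batch_size >= 2L)
  half <- batch_size %/% 2L
  with_seed(seed, {
    neg <- sample(neg)
    n_batches <- ceiling(length(neg) / half)
    lapply(seq_len(n_batches), function(b) {
      take <- neg[(((b - 1L) * half) + 1L):min(b * half, length(neg))]
      boot_pos <- pos[sample.int(length(pos), length(take), replace = TRUE)]
      sample(c(take, boot_pos))
    })
  })
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a recurrent off-target classifier
#'
#' Runs `genome$epochs` epochs of class-balanced bootstrap mini-batches
#' (batch size, learning rate and dropout from the genome), minimizing
#' two-class cross-entropy with Adam (moment parameters at their
#' conventional 0.9/0.999 defaults). All randomness (batch composition,
#' dropout masks) derives from `seed`, so identical calls produce identical
#' trained parameters.
#'
#' @param model a [build_model()] classifier
#' @param train data.frame with `sgrna`, `dna`, `label`
#' @param validation optional data.frame; when given, validation AUPRC is
#'   recorded per epoch
#' @param seed integer seed for batch/dropout randomness
#' @param verbose print per-epoch progress
#' @return the model with trained parameters and a `history` data.frame
#'   (`epoch`, `loss`, `val_auprc`)
#' @export
train_model <- function(model, train, validation = NULL, seed = 1L,
                        verbose = FALSE) {
  g <- model$genome
  stopifnot(is.data.frame(train), all(c("sgrna", "dna", "label") %in% names(train)))
  x <- encode_dataset(train, channels = model$spec$channels)
  y <- as.integer(train$label)
  xval <- if (!is.null(validation)) {
    encode_dataset(validation, channels = model$spec$channels)
  }
  params <- model$params
  state <- adam_init(params)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_auprc = numeric(0))
  for (epoch in seq_len(g$epochs)) {
    batches <- balanced_batches(y, g$batch_size,
                                seed = derive_seed(seed, "batches", epoch))
    epoch_loss <- 0
    with_seed(derive_seed(seed, "dropout", epoch), {
      for (b in batches) {
        mtmp <- model
        mtmp$params <- params
        fwd <- model_forward(mtmp, x[b, , , drop = FALSE], training = TRUE)
        lg <- ce_loss_grad(fwd$logits, y[b])
        if (!is.finite(lg$loss)) {
          abort_cf(sprintf("training diverged at epoch %d", epoch),
                   "TrainingDiverged")
        }
        bwd <- model_backward(mtmp, fwd$cache, lg$dlogits)
        upd <- adam_step(params, bwd$grads, state, lr = g$learning_rate)
        params <- upd$params
        state <- upd$state
        epoch_loss <- epoch_loss + lg$loss
      }
    })
    model$params <- params
    val_auprc <- NA_real_
    if (!is.null(xval)) {
      sc <- softmax(predict_batched(model, xval))[, 2L]
      val_auprc <- average_precision(sc, validation$label)
    }
    history <- rbind(history, data.frame(
      epoch = epoch, loss = epoch_loss / length(batches), val_auprc = val_auprc
    ))
    if (verbose) {
      message(sprintf("epoch %3d | loss %.4f | val AUPRC %s", epoch,
                      epoch_loss / length(batches),
                      ifelse(is.na(val_auprc), "-", sprintf("%.4f", val_auprc))))
    }
  }
  model$history <- history
  model
}
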