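# Exact reverse-mode gradients for the recurrent classifier. One backward
# pass returns gradients for every parameter AND for the encoded input --
# the latter drives integrated gradients. Correctness is pinned by
# finite-difference tests over all cell types and stackings.

rnn_dir_backward <- function(x, fwd, Wx, Wh, type, dh_seq, dh_last) {
  d <- dim(x)
  B <- d[1]; TT <- d[2]
  gm <- GATE_MULT[[type]]
  H <- ncol(Wh) / gm
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
  torder <- fwd$torder
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(gm * H)
  dx <- array(0, d)
  dh_carry <- dh_last
  dc_carry <- matrix(0, B, H)
  for (idx in rev(seq_along(torder))) {
    t <- torder[idx]
    h_prev <- if (idx > 1L) tslice(fwd$h_seq, torder[idx - 1L]) else matrix(0, B, H)
    dh <- dh_carry + tslice(dh_seq, t)
    xt <- tslice(x, t)
    if (type == "RNN") {
      ht <- tslice(fwd$gates, t)
      dz <- dh * (1 - ht * ht)
      dWx <- dWx + crossprod(xt, dz)
      dWh <- dWh + crossprod(h_prev, dz)
      db <- db + colSums(dz)
      dx[, t, ] <- dz %*% t(Wx)
      dh_carry <- dz %*% t(Wh)
    } else if (type == "LSTM") {
      gt <- tslice(fwd$gates, t)
      ig <- gt[, i1, drop = FALSE]; fg <- gt[, i2, drop = FALSE]
      gg <- gt[, i3, drop = FALSE]; og <- gt[, i4, drop = FALSE]
      ct <- tslice(fwd$c_seq, t)
      c_prev <- if (idx > 1L) tslice(fwd$c_seq, torder[idx - 1L]) else matrix(0, B, H)
      tc <- tanh(ct)
      dog <- dh * tc
      dct <- dc_carry + dh * og * (1 - tc * tc)
      dig <- dct * gg
      dfg <- dct * c_prev
      dgg <- dct * ig
      dc_carry <- dct * fg
      dz <- cbind(dig * ig * (1 - ig), dfg * fg * (1 - fg),
                  dgg * (1 - gg * gg), dog * og * (1 - og))
      dWx <- dWx + crossprod(xt, dz)
      dWh <- dWh + crossprod(h_prev, dz)
      db <- db + colSums(dz)
      dx[, t, ] <- dz %*% t(Wx)
      dh_carry <- dz %*% t(Wh)
    } else { # GRU
      gt <- tslice(fwd$gates, t)
      rg <- gt[, i1, drop = FALSE]; zg <- gt[, i2, drop = FALSE]
      ng <- gt[, i3, drop = FALSE]
      hpn <- tslice(fwd$hp_n, t)
      dzg <- dh * (h_prev - ng)
      dng <- dh * (1 - zg)
      dn_pre <- dng * (1 - ng * ng)
      drg <- dn_pre * hpn
      dz_pre <- dzg * zg * (1 - zg)
      dr_pre <- drg * rg * (1 - rg)
      dzx <- cbind(dr_pre, dz_pre, dn_pre)            # input-side preacts
      dhp <- cbind(dr_pre, dz_pre, dn_pre * rg)       # hidden-side preacts
      dWx <- dWx + crossprod(xt, dzx)
      dWh <- dWh + crossprod(h_prev, dhp)
      db <- db + colSums(dzx)
      dx[, t, ] <- dzx %*% t(Wx)
      dh_carry <- dh * zg + dhp %*% t(Wh)
    }
  }
  list(dWx = dWx, dWh = dWh, db = db, dx = dx)
}

# Backward through the whole network given d(loss)/d(logits).
# Returns list(grads = <named like params>, dx = [B,T,C],
#              fc_act_grads = per-dense-layer d(objective)/d(post-ReLU act)).
model_backward <- function(model, cache, dlogits, want_fc_act_grads = FALSE) {
  sp <- model$spec
  p <- model$params
  B <- nrow(dlogits)
  grads <- list()
  grads[["out.W"]] <- crossprod(cache$out_input, dlogits)
  grads[["out.b"]] <- colSums(dlogits)
  da <- dlogits %*% t(p[["out.W"]])
  fc_act_grads <- if (want_fc_act_grads) vector("list", length(sp$fc_widths)) else NULL
  for (j in rev(seq_along(sp$fc_widths))) {
    layer <- cache$fc[[j]]
    if (!is.null(layer$mask)) da <- da * layer$mask
    if (want_fc_act_grads) fc_act_grads[[j]] <- da
    dz <- da * (layer$z > 0)
    grads[[sprintf("fc%d.W", j)]] <- crossprod(layer$input, dz)
    grads[[sprintf("fc%d.b", j)]] <- colSums(dz)
    da <- dz %*% t(p[[sprintf("fc%d.W", j)]])
  }
  # da is now d/d(handoff) = grad of the top layer's final states
  H <- sp$hidden_size
  dirs <- c("fw", "bw")[seq_len(sp$ndir)]
  dh_last <- list(fw = da[, seq_len(H), drop = FALSE])
  if (sp$ndir == 2L) dh_last$bw <- da[, H + seq_len(H), drop = FALSE]
  dseq_next <- NULL # gradient flowing into this layer's h_seq from above
  for (l in rev(seq_len(sp$n_recurrent_layers))) {
    layer <- cache$layers[[l]]
    TT <- GUIDE_LENGTH
    width <- H * sp$ndir
    dh_seq_full <- if (is.null(dseq_next)) array(0, c(B, TT, width)) else dseq_next
    if (!is.null(layer$drop_mask)) dh_seq_full <- dh_seq_full * layer$drop_mask
    dx_acc <- NULL
    for (d in dirs) {
      sel <- if (d == "fw") seq_len(H) else H + seq_len(H)
      dh_seq_d <- dh_seq_full[, , sel, drop = FALSE]
      dlast <- if (l == sp$n_recurrent_layers) dh_last[[d]] else matrix(0, B, H)
      res <- rnn_dir_backward(
        layer$input, layer$dirs[[d]],
        p[[sprintf("rec%d.%s.Wx", l, d)]],
        p[[sprintf("rec%d.%s.Wh", l, d)]],
        sp$cell_type, dh_seq_d, dlast
      )
      grads[[sprintf("rec%d.%s.Wx", l, d)]] <- res$dWx
      grads[[sprintf("rec%d.%s.Wh", l, d)]] <- res$dWh
      grads[[sprintf("rec%d.%s.b", l, d)]] <- res$db
      dx_acc <- if (is.null(dx_acc)) res$dx else dx_acc + res$dx
    }
    dseq_next <- dx_acc
  }
  list(grads = grads, dx = dseq_next, fc_act_grads = fc_act_grads)
}

# cross-entropy over 2-class logits; returns loss and d(loss)/d(logits)
ce_loss_grad <- function(logits, labels) {
  B <- nrow(logits)
  probs <- softmax(logits)
  idx <- cbind(seq_len(B), labels + 1L)
  loss <- -mean(log(pmax(probs[idx], 1e-300)))
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / B)
}
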