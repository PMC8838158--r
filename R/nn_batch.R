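# Vectorised batch forward/backward used by the trainer.  Operates on a
# design matrix X (n beats x 48 columns); column (r-1)*24 + c holds element
# (r, c) of the 2x24 tensor (row-major), i.e. a tensor row equals
# as.vector(t(tensor)).  Must stay numerically identical to forward() --
# tested against it.

# Index tables for the two 1x7 convolution stages (windows x taps).
# conv1: input 2x24 -> windows (r-1)*18 + j, j = 1..18.
# conv3: input 2x9  -> windows (r-1)*3 + j,  j = 1..3.
conv_index_table <- function(in_cols, out_cols) {
  P <- matrix(0L, 2L * out_cols, KERNEL_LEN)
  for (r in 1:2) {
    for (j in seq_len(out_cols)) {
      P[(r - 1L) * out_cols + j, ] <- (r - 1L) * in_cols + j + 0:(KERNEL_LEN - 1L)
    }
  }
  P
}

.nn_idx <- local({
  P1 <- conv_index_table(24L, 18L)
  P3 <- conv_index_table(9L, 3L)
  # pool 1x2 over the 2x18 conv1 map: output col (r-1)*9 + i
  i2a <- integer(18L); i2b <- integer(18L)
  for (r in 1:2) {
    for (i in 1:9) {
      o <- (r - 1L) * 9L + i
      i2a[o] <- (r - 1L) * 18L + 2L * i - 1L
      i2b[o] <- (r - 1L) * 18L + 2L * i
    }
  }
  # pool 1x3 over the 2x3 conv3 map: output col r <- input cols (r-1)*3 + 1..3
  i3 <- rbind(c(1L, 2L, 3L), c(4L, 5L, 6L))
  list(P1 = P1, P3 = P3, i2a = i2a, i2b = i2b, i3 = i3)
})

conv_batch <- function(X, P, kernel) {
  out <- matrix(0, nrow(X), nrow(P))
  for (t in seq_len(KERNEL_LEN)) {
    out <- out + X[, P[, t], drop = FALSE] * kernel[t]
  }
  out
}

# Forward over a batch, keeping everything backprop needs.
nn_forward_batch <- function(X, w) {
  ix <- .nn_idx
  Y1 <- lapply(1:3, function(k) conv_batch(X, ix$P1, w$conv1[k, ]))
  A1 <- lapply(Y1, function(y) y * (y > 0))
  # pool 1x2 with leftmost-wins ties
  take1 <- lapply(A1, function(a) a[, ix$i2a, drop = FALSE] >= a[, ix$i2b, drop = FALSE])
  M <- lapply(1:3, function(k) {
    a <- A1[[k]]
    ifelse(take1[[k]], a[, ix$i2a, drop = FALSE], a[, ix$i2b, drop = FALSE])
  })
  Z <- w$conv2[1L] * M[[1L]] + w$conv2[2L] * M[[2L]] + w$conv2[3L] * M[[3L]]
  A2 <- Z * (Z > 0)
  Y3 <- lapply(1:3, function(k) conv_batch(A2, ix$P3, w$conv3[k, ]))
  A3 <- lapply(Y3, function(y) y * (y > 0))
  # pool 1x3 per row of each channel
  pool3 <- lapply(A3, function(a) {
    va <- a[, ix$i3[, 1L], drop = FALSE]
    vb <- a[, ix$i3[, 2L], drop = FALSE]
    vc <- a[, ix$i3[, 3L], drop = FALSE]
    ta <- va >= vb & va >= vc
    tb <- !ta & (vb >= vc)
    list(val = ifelse(ta, va, ifelse(tb, vb, vc)), ta = ta, tb = tb)
  })
  Fm <- do.call(cbind, lapply(pool3, `[[`, "val"))     # n x 6, channel-major
  H0 <- Fm %*% w$fc1
  H <- H0 * (H0 > 0)
  S <- H %*% w$fc2
  list(X = X, Y1 = Y1, A1 = A1, take1 = take1, M = M, Z = Z, A2 = A2,
       Y3 = Y3, A3 = A3, pool3 = pool3, Fm = Fm, H0 = H0, H = H, S = S)
}

# Backward pass: dS is dLoss/dS (n x 6).  Returns gradients shaped like
# the weight groups.  Subgradient 0 at ReLU kinks and leftmost routing at
# pooling ties, matching the forward masks.
nn_backward_batch <- function(cache, dS, w) {
  ix <- .nn_idx
  dW2 <- crossprod(cache$H, dS)                 # 21 x 6
  dH <- (dS %*% t(w$fc2)) * (cache$H0 > 0)
  dW1 <- crossprod(cache$Fm, dH)                # 6 x 21
  dF <- dH %*% t(w$fc1)                         # n x 6
  dconv3 <- matrix(0, 3, KERNEL_LEN)
  dA2 <- matrix(0, nrow(dS), 18L)
  for (k in 1:3) {
    p <- cache$pool3[[k]]
    dPk <- dF[, (k - 1L) * 2L + 1:2, drop = FALSE]   # n x 2 (rows)
    dA3 <- matrix(0, nrow(dS), 6L)
    dA3[, ix$i3[, 1L]] <- dPk * p$ta
    dA3[, ix$i3[, 2L]] <- dPk * p$tb
    dA3[, ix$i3[, 3L]] <- dPk * (!p$ta & !p$tb)
    dY3 <- dA3 * (cache$Y3[[k]] > 0)
    for (t in seq_len(KERNEL_LEN)) {
      dconv3[k, t] <- sum(dY3 * cache$A2[, ix$P3[, t], drop = FALSE])
      # within one tap the window->input map is injective, so plain
      # indexed addition is safe
      dA2[, ix$P3[, t]] <- dA2[, ix$P3[, t], drop = FALSE] + dY3 * w$conv3[k, t]
    }
  }
  dZ <- dA2 * (cache$Z > 0)
  dconv2 <- vapply(1:3, function(c) sum(dZ * cache$M[[c]]), numeric(1))
  dconv1 <- matrix(0, 3, KERNEL_LEN)
  for (k in 1:3) {
    dMk <- dZ * w$conv2[k]
    dA1 <- matrix(0, nrow(dS), 36L)
    dA1[, ix$i2a] <- dMk * cache$take1[[k]]
    dA1[, ix$i2b] <- dMk * (!cache$take1[[k]])
    dY1 <- dA1 * (cache$Y1[[k]] > 0)
    for (t in seq_len(KERNEL_LEN)) {
      dconv1[k, t] <- sum(dY1 * cache$X[, ix$P1[, t], drop = FALSE])
    }
  }
  list(conv1 = dconv1, conv2 = dconv2, conv3 = dconv3, fc1 = dW1, fc2 = dW2)
}

# Mean softmax cross-entropy and its gradient w.r.t. all weights.
nn_loss_grad <- function(X, y_idx1, w) {
  cache <- nn_forward_batch(X, w)
  n <- nrow(X)
  P <- softmax_rows(cache$S)
  loss <- -mean(log(pmax(P[cbind(seq_len(n), y_idx1)], 1e-300)))
  dS <- P
  dS[cbind(seq_len(n), y_idx1)] <- dS[cbind(seq_len(n), y_idx1)] - 1
  dS <- dS / n
  list(loss = loss, grads = nn_backward_batch(cache, dS, w), scores = cache$S)
}

softmax_rows <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

# Batch prediction: class codes via argmax with lowest-index tie-break.
predict_batch <- function(X, w) {
  S <- nn_forward_batch(X, w)$S
  BEAT_CLASSES[max.col(S, ties.method = "first")]
}
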