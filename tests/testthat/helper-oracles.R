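# Independent brute-force oracles.  These deliberately use naive nested
# loops and avoid every code path of the package implementation.

oracle_conv_rowwise <- function(map, kernel) {
  nr <- nrow(map)
  nc <- ncol(map) - 6L
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (j in seq_len(nc)) {
      s <- 0
      for (k in 0:6) s <- s + map[r, j + k] * kernel[k + 1L]
      out[r, j] <- s
    }
  }
  out
}

oracle_conv_1x1 <- function(maps, weights) {
  out <- matrix(0, nrow(maps[[1]]), ncol(maps[[1]]))
  for (r in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      for (c in 1:3) out[r, j] <- out[r, j] + weights[c] * maps[[c]][r, j]
    }
  }
  out
}

oracle_maxpool_row <- function(map, width) {
  n <- ncol(map) %/% width
  out <- matrix(NA_real_, nrow(map), n)
  for (r in seq_len(nrow(map))) {
    for (j in seq_len(n)) {
      out[r, j] <- max(map[r, ((j - 1L) * width + 1L):(j * width)])
    }
  }
  out
}

oracle_dense <- function(x, W) {
  out <- numeric(ncol(W))
  for (j in seq_len(ncol(W))) {
    s <- 0
    for (i in seq_len(nrow(W))) s <- s + x[i] * W[i, j]
    out[j] <- s
  }
  out
}

# Straight-line composition of the layer oracles: the full forward pass.
oracle_forward_scores <- function(input, w) {
  rl <- function(m) {
    m[m < 0] <- 0
    m
  }
  a1 <- lapply(1:3, function(k) rl(oracle_conv_rowwise(input, w$conv1[k, ])))
  p1 <- lapply(a1, oracle_maxpool_row, width = 2L)
  a2 <- rl(oracle_conv_1x1(p1, w$conv2))
  a3 <- lapply(1:3, function(k) rl(oracle_conv_rowwise(a2, w$conv3[k, ])))
  p3 <- lapply(a3, oracle_maxpool_row, width = 3L)
  f <- c(p3[[1]][1, 1], p3[[1]][2, 1], p3[[2]][1, 1], p3[[2]][2, 1],
         p3[[3]][1, 1], p3[[3]][2, 1])
  h <- rl(matrix(oracle_dense(f, w$fc1), 1))[1, ]
  oracle_dense(h, w$fc2)
}

# Quantization oracle: explicit scaling, floor-based round-half-to-even,
# explicit clipping.  Shares no code with quantize().
oracle_quantize_one <- function(x, total_bits, frac_bits) {
  y <- x * 2^frac_bits
  lo <- floor(y)
  frac <- y - lo
  v <- if (frac > 0.5) {
    lo + 1
  } else if (frac < 0.5) {
    lo
  } else {
    if (lo %% 2 == 0) lo else lo + 1
  }
  hi_lim <- 2^(total_bits - 1) - 1
  lo_lim <- -2^(total_bits - 1)
  min(max(v, lo_lim), hi_lim)
}

oracle_confusion <- function(labels, predictions) {
  cls <- c("N", "L", "R", "V", "A", "/")
  out <- matrix(0L, 6, 6)
  for (i in seq_along(labels)) {
    r <- which(cls == labels[i])
    c <- which(cls == predictions[i])
    out[r, c] <- out[r, c] + 1L
  }
  out
}

random_weights <- function(scale = 0.5) {
  model_weights(
    conv1 = matrix(runif(21, -scale, scale), 3, 7),
    conv2 = runif(3, -scale, scale),
    conv3 = matrix(runif(21, -scale, scale), 3, 7),
    fc1 = matrix(runif(126, -scale, scale), 6, 21),
    fc2 = matrix(runif(126, -scale, scale), 21, 6)
  )
}

random_input <- function() {
  matrix(runif(48, -1, 1), 2, 24)
}

# Small cached dataset shared by several test files.
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(30, 10, generator_config(seed = 42))
    }
    cache
  }
})
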