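#' @title Floating-point reference network
#' @description Layer primitives and the forward pass of the fixed
#'   six-class beat classifier.  The architecture is deliberately rigid:
#'   2x24 input -> conv 3@1x7 -> ReLU -> maxpool 1x2 -> conv 1x1 (3->1
#'   channel) -> ReLU -> conv 3@1x7 -> ReLU -> maxpool 1x3 -> flatten(6)
#'   -> dense 6x21 -> ReLU -> dense 21x6 -> argmax.  297 weights in
#'   total, no bias terms anywhere.
#' @name model_core
NULL

KERNEL_LEN <- 7L

#' Construct and validate a weight set
#'
#' @param conv1 3x7 numeric matrix, first-layer kernels (one per row).
#' @param conv2 Numeric length-3 vector, the 1x1 channel-mixing weights.
#' @param conv3 3x7 numeric matrix, third-layer kernels (one per row);
#'   every kernel is applied to the single post-1x1 feature map.
#' @param fc1 6x21 numeric matrix (input nodes x hidden nodes).
#' @param fc2 21x6 numeric matrix (hidden nodes x output nodes).
#' @return An object of class `model_weights`.
#' @seealso [init_model_weights()], [count_parameters()]
#' @export
model_weights <- function(conv1, conv2, conv3, fc1, fc2) {
  w <- list(
    conv1 = as.matrix(conv1),
    conv2 = as.numeric(conv2),
    conv3 = as.matrix(conv3),
    fc1 = as.matrix(fc1),
    fc2 = as.matrix(fc2)
  )
  class(w) <- "model_weights"
  validate_model_weights(w)
  w
}

validate_model_weights <- function(w) {
  stopifnot(inherits(w, "model_weights"))
  if (!identical(dim(w$conv1), c(3L, 7L))) stop("conv1 must be 3x7")
  if (length(w$conv2) != 3L) stop("conv2 must have length 3")
  if (!identical(dim(w$conv3), c(3L, 7L))) stop("conv3 must be 3x7")
  if (!identical(dim(w$fc1), c(6L, 21L))) stop("fc1 must be 6x21")
  if (!identical(dim(w$fc2), c(21L, 6L))) stop("fc2 must be 21x6")
  vals <- unlist(w[c("conv1", "conv2", "conv3", "fc1", "fc2")])
  if (length(vals) != 297L) stop("weight set must hold exactly 297 scalars")
  if (!all(is.finite(vals))) stop("weights must be finite")
  invisible(w)
}

#' @export
print.model_weights <- function(x, ...) {
  cnt <- count_parameters(x)
  cat("<model_weights> 297-parameter beat classifier\n")
  cat(sprintf("  conv1 3@1x7: %d   conv2 1x1: %d   conv3 3@1x7: %d\n",
              cnt$conv1, cnt$conv2, cnt$conv3))
  cat(sprintf("  fc1 6x21: %d   fc2 21x6: %d   total: %d\n",
              cnt$fc1, cnt$fc2, cnt$total))
  invisible(x)
}

#' Glorot-uniform weight initialisation
#'
#' Each group is drawn from U(-a, a) with a = sqrt(6 / (fan_in + fan_out)),
#' using the kernel taps times channel counts as fans for the convolutional
#' groups.  The three 1x1 channel-mixing weights are folded to their
#' absolute value: they act on non-negative (post-ReLU) maps feeding a
#' single channel, and a sign-mixed draw can zero that bottleneck and
#' kill every gradient in the network.
#'
#' @param seed Integer RNG seed (mandatory for reproducibility).
#' @return A `model_weights` object.
#' @export
init_model_weights <- function(seed = 1234L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  with_preserved_rng({
    set.seed(as.integer(seed))
    lim <- function(fan_in, fan_out) sqrt(6 / (fan_in + fan_out))
    u <- function(n, a) stats::runif(n, -a, a)
    model_weights(
      conv1 = matrix(u(21, lim(7, 21)), 3, 7),
      conv2 = abs(u(3, lim(3, 1))),
      conv3 = matrix(u(21, lim(7, 21)), 3, 7),
      fc1 = matrix(u(126, lim(6, 21)), 6, 21),
      fc2 = matrix(u(126, lim(21, 6)), 21, 6)
    )
  })
}

#' Per-layer and total parameter counts
#'
#' @param w A `model_weights` object (defaults to a zero-initialised one,
#'   so the counts can be queried without weights at hand).
#' @return Named list with `conv1`, `conv2`, `conv3`, `fc1`, `fc2`, `total`.
#' @examples
#' count_parameters()$total  # 297
#' @export
count_parameters <- function(w = NULL) {
  if (is.null(w)) {
    w <- model_weights(matrix(0, 3, 7), numeric(3), matrix(0, 3, 7),
                       matrix(0, 6, 21), matrix(0, 21, 6))
  }
  validate_model_weights(w)
  out <- list(
    conv1 = length(w$conv1),
    conv2 = length(w$conv2),
    conv3 = length(w$conv3),
    fc1 = length(w$fc1),
    fc2 = length(w$fc2)
  )
  out$total <- sum(unlist(out))
  out
}

#' Row-wise valid 1x7 convolution
#'
#' Slides a 1x7 kernel along each row of a 2xC map without padding
#' (cross-correlation; no kernel flip), producing a 2x(C-6) map.
#'
#' @param map Numeric matrix with at least 7 columns.
#' @param kernel Numeric vector of length 7.
#' @return Matrix with the same number of rows and `ncol(map) - 6` columns.
#' @export
conv_rowwise <- function(map, kernel) {
  map <- as.matrix(map)
  if (length(kernel) != KERNEL_LEN) stop("kernel must have length 7")
  C <- ncol(map)
  if (C < KERNEL_LEN) {
    stop(sprintf("invalid shape: conv_rowwise needs >= 7 columns, got %d", C))
  }
  nc <- C - KERNEL_LEN + 1L
  out <- matrix(0, nrow(map), nc)
  for (t in seq_len(KERNEL_LEN)) {
    out <- out + map[, t:(t + nc - 1L), drop = FALSE] * kernel[t]
  }
  out
}

#' 1x1 channel-mixing convolution (3 channels to 1)
#'
#' @param maps List of exactly 3 numeric matrices of identical shape.
#' @param weights Numeric vector of length 3.
#' @return A single matrix: the per-element weighted sum of the channels.
#' @export
conv_1x1 <- function(maps, weights) {
  if (!is.list(maps) || length(maps) != 3L) {
    stop("invalid shape: conv_1x1 expects exactly 3 input channels")
  }
  if (length(weights) != 3L) stop("conv_1x1 needs 3 weights")
  d <- dim(as.matrix(maps[[1L]]))
  for (m in maps) {
    if (!identical(dim(as.matrix(m)), d)) {
      stop("invalid shape: conv_1x1 channels must share one shape")
    }
  }
  weights[1L] * maps[[1L]] + weights[2L] * maps[[2L]] + weights[3L] * maps[[3L]]
}

#' Rectified linear unit
#'
#' @param x Numeric vector, matrix or array.
#' @return `max(0, x)` elementwise, same shape.
#' @export
relu <- function(x) {
  pmax(x, 0)
}

#' Non-overlapping row-wise max pooling
#'
#' Left-aligned windows of width 2 or 3 along each row; trailing columns
#' that do not fill a window are dropped.  Ties take the leftmost element
#' (relevant only for gradient routing; the max itself is unambiguous).
#'
#' @param map Numeric matrix.
#' @param width Pooling width, 2 or 3.
#' @return Matrix with `floor(ncol(map) / width)` columns.
#' @export
maxpool_row <- function(map, width) {
  map <- as.matrix(map)
  if (!width %in% c(2L, 3L)) stop("pooling width must be 2 or 3")
  C <- ncol(map)
  if (C < width) {
    stop(sprintf("invalid shape: maxpool needs >= %d columns, got %d", width, C))
  }
  n <- C %/% width
  out <- map[, seq(1L, by = width, length.out = n), drop = FALSE]
  for (t in 2:width) {
    out <- pmax(out, map[, seq(t, by = width, length.out = n), drop = FALSE])
  }
  out
}

#' Dense (fully connected) layer without bias
#'
#' @param x Numeric vector of length `nrow(W)`.
#' @param W Weight matrix, input nodes in rows, output nodes in columns.
#' @return Numeric vector of length `ncol(W)`.
#' @export
dense <- function(x, W) {
  W <- as.matrix(W)
  if (length(x) != nrow(W)) {
    stop(sprintf("invalid shape: dense expects input length %d, got %d",
                 nrow(W), length(x)))
  }
  as.vector(x %*% W)
}

# Flatten the three pooled 2x1 conv3 maps into the 6-vector fed to fc1.
# Order: channel-major, row within channel: (ch1 r1, ch1 r2, ch2 r1, ...).
flatten_pooled <- function(maps) {
  unlist(lapply(maps, function(m) m[, 1L]), use.names = FALSE)
}

#' Forward pass of the beat classifier
#'
#' Runs the full pipeline on a single 2x24 input tensor and returns the
#' six raw output scores together with the predicted class (argmax,
#' lowest index on ties).  Scores are pre-softmax; at inference time the
#' softmax is a monotone map and only the argmax matters.
#'
#' @param input 2x24 numeric matrix (one preprocessed beat).
#' @param w A `model_weights` object.
#' @param keep_activations If `TRUE`, attach all intermediate feature maps
#'   as the `activations` element (for debugging and verification).
#' @return List with `scores` (named numeric of length 6), `predicted`
#'   (class code) and optionally `activations`.
#' @examples
#' w <- init_model_weights(1)
#' x <- matrix(sin(1:48 / 3), 2, 24, byrow = TRUE)
#' forward(x, w)$predicted
#' @export
forward <- function(input, w, keep_activations = FALSE) {
  input <- as.matrix(input)
  if (!identical(dim(input), c(2L, 24L))) {
    stop("invalid shape: input tensor must be 2x24")
  }
  if (!all(is.finite(input))) stop("input tensor must be finite")
  validate_model_weights(w)

  a1 <- lapply(1:3, function(k) relu(conv_rowwise(input, w$conv1[k, ])))
  p1 <- lapply(a1, maxpool_row, width = 2L)           # 3 @ 2x9
  a2 <- relu(conv_1x1(p1, w$conv2))                    # 1 @ 2x9
  a3 <- lapply(1:3, function(k) relu(conv_rowwise(a2, w$conv3[k, ])))
  p3 <- lapply(a3, maxpool_row, width = 3L)           # 3 @ 2x1
  f <- flatten_pooled(p3)                              # 6
  h <- relu(dense(f, w$fc1))                           # 21
  s <- dense(h, w$fc2)                                 # 6
  names(s) <- BEAT_CLASSES
  out <- list(scores = s, predicted = BEAT_CLASSES[which.max(s)])
  if (keep_activations) {
    out$activations <- list(conv1 = a1, pool1 = p1, conv2 = a2,
                            conv3 = a3, pool3 = p3, flat = f, fc1 = h)
  }
  out
}

# Run RNG-consuming code without disturbing the caller's RNG stream.
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}
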