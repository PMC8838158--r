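#' @title Bit-accurate datapath simulator
#' @description Behavioural model of the resource-shared inference
#'   engine: one seven-lane multiply-accumulate processing element (PE),
#'   one ReLU unit with a partial-sum accumulator, one max-pooling unit,
#'   one softmax/argmax unit with six result registers, and a 54-register
#'   control buffer.  Six multiplexer select signals (S1..S6) route data
#'   between the units; every network layer is a schedule of unit
#'   invocations under one fixed S-assignment.  Only invocation counts
#'   are modelled, not clock cycles.
#' @name quantized_datapath
NULL

DP_LAYER_NAMES <- c("conv1", "maxpool1", "conv1x1", "conv3", "maxpool2",
                    "flatten", "fc1", "fc2")

#' Multiplexer schedule for one layer
#'
#' Returns the select-signal assignment driving the shared units while a
#' given layer executes.  `NA` means don't-care: the signal is not
#' consulted by that layer.  S1..S4 are single bits; S5 and S6 are 2-bit
#' codes given as strings ("00".."11").  During the 1x1 convolution
#' (layer 3) S5 cycles through "00", "01", "10" to select the input
#' channel of each partial sum.
#'
#' @param layer_index Integer in 1..8 (conv, pool, 1x1 conv, conv, pool,
#'   flatten, fc, fc).
#' @return An object of class `mux_state` with fields `layer`, `name`,
#'   `S1`..`S4` (integer bit or `NA`), `S5` (character vector or `NA`),
#'   `S6` (character or `NA`).
#' @examples
#' schedule_layer(1)   # S1 = 0, S2 = 1, rest don't-care
#' @export
schedule_layer <- function(layer_index) {
  if (!is.numeric(layer_index) || length(layer_index) != 1L ||
      is.na(layer_index) || layer_index < 1 || layer_index > 8 ||
      layer_index != round(layer_index)) {
    stop("layer_index must be a single integer in 1..8")
  }
  i <- as.integer(layer_index)
  rows <- list(
    list(S1 = 0L, S2 = 1L, S3 = NA, S4 = NA, S5 = NA, S6 = NA),
    list(S1 = NA, S2 = NA, S3 = 1L, S4 = 1L, S5 = NA, S6 = NA),
    list(S1 = 1L, S2 = 0L, S3 = NA, S4 = 0L,
         S5 = c("00", "01", "10"), S6 = "00"),
    list(S1 = 1L, S2 = 1L, S3 = NA, S4 = NA, S5 = NA, S6 = "10"),
    list(S1 = NA, S2 = NA, S3 = 0L, S4 = 1L, S5 = NA, S6 = NA),
    list(S1 = NA, S2 = NA, S3 = NA, S4 = NA, S5 = NA, S6 = NA),
    list(S1 = 1L, S2 = 1L, S3 = NA, S4 = 0L, S5 = NA, S6 = "11"),
    list(S1 = 1L, S2 = NA, S3 = NA, S4 = NA, S5 = NA, S6 = "01")
  )
  st <- rows[[i]]
  st$layer <- i
  st$name <- DP_LAYER_NAMES[i]
  class(st) <- "mux_state"
  st
}

#' @export
print.mux_state <- function(x, ...) {
  fmt1 <- function(v) if (length(v) == 1 && is.na(v)) "x" else paste(v, collapse = "/")
  cat(sprintf("<mux_state> layer %d (%s): S1=%s S2=%s S3=%s S4=%s S5=%s S6=%s\n",
              x$layer, x$name, fmt1(x$S1), fmt1(x$S2), fmt1(x$S3),
              fmt1(x$S4), fmt1(x$S5), fmt1(x$S6)))
  invisible(x)
}

#' Processing element: 7-lane multiply-accumulate
#'
#' Performs exactly seven integer multiplications and six additions and
#' returns the full-precision sum (no intermediate rounding).  Unused
#' lanes must be padded with zeros.  The implementation verifies that
#' every product and the sum stay within the exactly-representable
#' double range, and saturates the result to the accumulator width.
#'
#' @param x Seven quantized input integers.
#' @param w Seven quantized coefficient integers (filter taps or dense
#'   weights, depending on the layer being scheduled).
#' @param acc_bits Accumulator width in bits (saturation bound).
#' @return The wide integer sum `sum(x * w)`.
#' @export
pe_execute <- function(x, w, acc_bits = 32L) {
  if (length(x) != 7L || length(w) != 7L) {
    stop("PE lanes must hold exactly 7 inputs and 7 coefficients")
  }
  p <- x * w
  s <- sum(p)
  if (max(abs(p)) >= 2^52 || abs(s) >= 2^52) {
    stop("PE accumulation exceeds exact-integer range; reduce word length")
  }
  amax <- 2^(acc_bits - 1L) - 1
  if (s > amax) s <- amax
  if (s < -amax - 1) s <- -amax - 1
  s
}

#' ReLU unit with 1x1 partial-sum accumulator
#'
#' With `s2 = 1` the unit takes one wide accumulator value (a finished
#' 1x7 convolution or dense sum), requantises it from Q(2f) to the
#' activation format Q(f) (round-to-nearest-even, saturating) and clamps
#' negatives to zero.  With `s2 = 0` it models the 1x1-convolution path:
#' the internal adder/register first accumulates the per-channel partial
#' sums (given together as `sums`), and ReLU + requantisation are applied
#' to the accumulated total.
#'
#' @param sums Wide integer sum (s2 = 1) or vector of per-channel wide
#'   partial sums (s2 = 0).
#' @param s2 Path select bit.
#' @param fmt Activation [fixed_point_format()].
#' @return One quantized activation integer (Q(f), non-negative).
#' @export
relu_unit <- function(sums, s2, fmt) {
  if (!s2 %in% c(0L, 1L)) stop("s2 must be 0 or 1")
  if (s2 == 1L && length(sums) != 1L) {
    stop("s2 = 1 expects a single finished sum")
  }
  total <- sum(sums)                 # exact wide accumulation
  q <- rshift_round_even(total, fmt$frac_bits, fmt)
  if (q < 0) q <- 0
  q
}

#' Max-pooling unit
#'
#' One shared comparator tree; `s3` selects the window width
#' (`s3 = 1` for 1x2, `s3 = 0` for 1x3).  Ties keep the leftmost value.
#'
#' @param values Quantized window values (2 or 3 of them).
#' @param s3 Width select bit.
#' @return The window maximum.
#' @export
maxpool_unit <- function(values, s3) {
  if (!s3 %in% c(0L, 1L)) stop("s3 must be 0 or 1")
  want <- if (s3 == 1L) 2L else 3L
  if (length(values) != want) {
    stop(sprintf("scheduling error: s3 = %d expects %d values, got %d",
                 s3, want, length(values)))
  }
  max(values)
}

#' Softmax/argmax unit
#'
#' The final dense layer needs 21 multiply-accumulates per output node;
#' the seven-lane PE therefore executes exactly three times per node, and
#' this unit's adder/register accumulates the three partial results into
#' the node registers R0..R5.  No exponential is computed at inference
#' time: the detection output is the index of the maximum register
#' (lowest index wins ties).
#'
#' @param partials 3 x 6 matrix (or list of six length-3 vectors) of wide
#'   partial sums, one column/element per output node in class order.
#' @return List with `values` (the six accumulated wide node values,
#'   named by class), `predicted` (class code) and `predicted_index`
#'   (0-based).
#' @export
softmax_unit <- function(partials) {
  if (is.list(partials)) {
    if (length(partials) != 6L) stop("need partials for exactly 6 nodes")
    lens <- lengths(partials)
    if (any(lens != 3L)) {
      stop("scheduling error: each output node needs exactly 3 PE results")
    }
    partials <- matrix(unlist(partials), nrow = 3L)
  }
  partials <- as.matrix(partials)
  if (!identical(dim(partials), c(3L, 6L))) {
    stop("scheduling error: each of the 6 output nodes needs exactly 3 PE results")
  }
  R <- colSums(partials)
  names(R) <- BEAT_CLASSES
  k <- which.max(R)
  list(values = R, predicted = BEAT_CLASSES[k], predicted_index = k - 1L)
}

#' Run one beat through the simulated datapath
#'
#' Executes all eight layers using only the five shared units under the
#' [schedule_layer()] multiplexer settings, tracking PE invocations per
#' layer and the peak number of values resident in the 54-register
#' control buffer.  Occupancy counts values that must persist between
#' unit invocations; values inside unit-internal pipeline registers (PE
#' lanes, the pooling comparator, the ReLU accumulator, the softmax
#' registers R0..R5) are not buffer residents.  Exceeding 54 residents
#' raises a simulation fault.
#'
#' @param input A [qtensor()] holding the 2x24 quantized beat (activation
#'   format), or a plain 2x24 real matrix which is then quantized with
#'   the weight format.
#' @param qw A `q_model_weights` object from [quantize_weights()].
#' @return List with `predicted` (class code), `predicted_index`,
#'   `scores` (dequantized node values), `scores_int` (wide Q(2f)
#'   integers), `pe_invocations` (named per-layer counts),
#'   `total_multiplications` (7 x total PE invocations) and
#'   `buffer_peak`.
#' @export
run_inference <- function(input, qw) {
  stopifnot(inherits(qw, "q_model_weights"))
  fmt <- qw$fmt
  if (!inherits(input, "qtensor")) {
    input <- qtensor(as.matrix(input), fmt)
  }
  X <- input$integers
  if (!identical(dim(X), c(2L, 24L))) stop("invalid shape: input must be 2x24")
  if (input$fmt$frac_bits != fmt$frac_bits) {
    stop("input and weight formats must share frac_bits")
  }
  acc <- fmt$acc_bits
  sched <- lapply(1:8, schedule_layer)
  pe_n <- integer(8L)
  live <- 0L
  peak <- 0L
  buf_push <- function(k) {
    live <<- live + k
    if (live > 54L) {
      stop("simulation fault: control buffer overflow (> 54 live values)")
    }
    if (live > peak) peak <<- live
  }
  buf_pop <- function(k) live <<- live - k

  # Layers 1 + 2: 1x7 convolution streams through ReLU straight into the
  # 1x2 pooling unit; only pooled values land in the buffer.
  s2_l1 <- sched[[1L]]$S2
  s3_l2 <- sched[[2L]]$S3
  pooled <- vector("list", 3L)
  for (k in 1:3) {
    kw <- qw$conv1[k, ]
    Pm <- matrix(0, 2L, 9L)
    for (r in 1:2) {
      for (i in 1:9) {
        pair <- numeric(2L)
        for (d in 1:2) {
          j <- 2L * (i - 1L) + d
          s <- pe_execute(X[r, j:(j + 6L)], kw, acc)
          pe_n[1L] <- pe_n[1L] + 1L
          pair[d] <- relu_unit(s, s2_l1, fmt)
        }
        Pm[r, i] <- maxpool_unit(pair, s3_l2)
        buf_push(1L)
      }
    }
    pooled[[k]] <- Pm
  }

  # Layer 3: 1x1 convolution.  S5 cycles the channel feeding the PE; the
  # three single-lane partial sums accumulate in the ReLU unit (S2 = 0).
  s2_l3 <- sched[[3L]]$S2
  n_chan <- length(sched[[3L]]$S5)
  A2 <- matrix(0, 2L, 9L)
  zeros6 <- numeric(6L)
  for (r in 1:2) {
    for (j in 1:9) {
      part <- numeric(n_chan)
      for (c in seq_len(n_chan)) {
        part[c] <- pe_execute(c(pooled[[c]][r, j], zeros6),
                              c(qw$conv2[c], zeros6), acc)
        pe_n[3L] <- pe_n[3L] + 1L
      }
      buf_pop(3L)
      A2[r, j] <- relu_unit(part, s2_l3, fmt)
      buf_push(1L)
    }
  }

  # Layer 4: second 1x7 convolution on the single 2x9 map.
  s2_l4 <- sched[[4L]]$S2
  A3 <- array(0, c(3L, 2L, 3L))
  for (k in 1:3) {
    kw <- qw$conv3[k, ]
    for (r in 1:2) {
      for (j in 1:3) {
        s <- pe_execute(A2[r, j:(j + 6L)], kw, acc)
        pe_n[4L] <- pe_n[4L] + 1L
        A3[k, r, j] <- relu_unit(s, s2_l4, fmt)
        buf_push(1L)
      }
    }
  }
  buf_pop(18L)   # the 2x9 conv inputs die once the layer completes

  # Layer 5: 1x3 pooling; layer 6: flatten is pure wiring.
  s3_l5 <- sched[[5L]]$S3
  Fv <- numeric(6L)
  idx <- 1L
  for (k in 1:3) {
    for (r in 1:2) {
      v <- maxpool_unit(A3[k, r, ], s3_l5)
      buf_pop(3L)
      buf_push(1L)
      Fv[idx] <- v
      idx <- idx + 1L
    }
  }

  # Layer 7: dense 6 -> 21; six active lanes, one zero-padded.
  s2_l7 <- sched[[7L]]$S2
  H <- numeric(21L)
  for (j in 1:21) {
    s <- pe_execute(c(Fv, 0), c(qw$fc1[, j], 0), acc)
    pe_n[7L] <- pe_n[7L] + 1L
    H[j] <- relu_unit(s, s2_l7, fmt)
    buf_push(1L)
  }
  buf_pop(6L)

  # Layer 8: dense 21 -> 6; three PE executions per node, accumulated in
  # the softmax unit's registers.
  partials <- matrix(0, 3L, 6L)
  for (node in 1:6) {
    for (p in 1:3) {
      lanes <- ((p - 1L) * 7L + 1L):(p * 7L)
      partials[p, node] <- pe_execute(H[lanes], qw$fc2[lanes, node], acc)
      pe_n[8L] <- pe_n[8L] + 1L
    }
  }
  buf_pop(21L)
  sm <- softmax_unit(partials)

  names(pe_n) <- DP_LAYER_NAMES
  list(
    predicted = sm$predicted,
    predicted_index = sm$predicted_index,
    scores = sm$values / 2^(2L * fmt$frac_bits),
    scores_int = sm$values,
    pe_invocations = pe_n,
    total_multiplications = 7L * sum(pe_n),
    buffer_peak = peak
  )
}

#' Worst-case quantization error bound on the output scores
#'
#' Propagates per-stage rounding errors through the network by interval
#' arithmetic: input quantization (q/2 per sample with q = 2^-frac_bits),
#' weight quantization (q/2 per coefficient), and one requantisation
#' (q/2) at every ReLU-unit output.  ReLU and max pooling are
#' non-expansive and add nothing.  Also tracks a bound on the activation
#' magnitudes so that the absence of saturation can be certified.
#'
#' @param w Float `model_weights`.
#' @param fmt [fixed_point_format()] used on the datapath.
#' @param input_bound Bound on the absolute value of input samples
#'   (preprocessed beats satisfy 1).
#' @return List with `score_bound` (bound on |dequantized datapath score
#'   - float score| per output node), `activation_bound` and
#'   `saturation_safe` (`TRUE` when no intermediate value can reach the
#'   saturation limits, making the bound valid).
#' @export
score_error_bound <- function(w, fmt, input_bound = 1) {
  validate_model_weights(w)
  q <- 2^(-fmt$frac_bits)
  h <- q / 2
  amax <- fmt_max_int(fmt) * q            # activation saturation level
  wmax <- max(abs(unlist(w[c("conv1", "conv2", "conv3", "fc1", "fc2")])))
  kb <- function(v) abs(v) + h            # quantized-coefficient magnitude bound

  M0 <- input_bound
  E0 <- h
  # conv1 (+ requant), per kernel; pooling keeps the max over channels
  E1 <- max(vapply(1:3, function(k) sum(kb(w$conv1[k, ])) * E0 +
                     7 * h * M0 + h, numeric(1)))
  M1 <- max(vapply(1:3, function(k) sum(kb(w$conv1[k, ])) * M0, numeric(1)))
  # 1x1 conv: exact wide accumulation, one requant
  E2 <- sum(kb(w$conv2)) * E1 + 3 * h * M1 + h
  M2 <- sum(kb(w$conv2)) * M1
  # conv3 (+ requant)
  E3 <- max(vapply(1:3, function(k) sum(kb(w$conv3[k, ])) * E2 +
                     7 * h * M2 + h, numeric(1)))
  M3 <- max(vapply(1:3, function(k) sum(kb(w$conv3[k, ])) * M2, numeric(1)))
  # fc1 (+ requant)
  c1 <- max(colSums(kb(w$fc1)))
  E4 <- c1 * E3 + 6 * h * M3 + h
  M4 <- c1 * M3
  # fc2: wide node values, dequantized, no requant
  c2 <- max(colSums(kb(w$fc2)))
  E5 <- c2 * E4 + 21 * h * M4
  M5 <- c2 * M4

  acc_max <- (2^(fmt$acc_bits - 1L) - 1) * q * q   # wide sums are Q(2f)
  safe <- (wmax + h) <= amax &&
    all(c(M0 + E0, M1 + E1, M2 + E2, M3 + E3, M4 + E4) <= amax) &&
    (M5 + E5) <= acc_max
  list(score_bound = E5,
       activation_bound = max(M1, M2, M3, M4) ,
       saturation_safe = safe)
}

#' Compare the fixed-point datapath with the float reference
#'
#' Runs every beat of a dataset through both [forward()] (float) and
#' [run_inference()] (fixed point, weights quantized to `fmt`) and
#' reports per-beat agreement of the predicted class together with the
#' score deviations.
#'
#' @param dataset A `beat_dataset` (see [generate_dataset()]).
#' @param w Float `model_weights` used by both paths.
#' @param fmt [fixed_point_format()] for the quantized path.
#' @param split Which split to use (`"test"`, `"train"` or `"all"`).
#' @return List of class `datapath_report` with `agreement` (fraction of
#'   beats with identical predicted class), `max_abs_score_dev`, `n`,
#'   `fmt` and `per_beat` (data frame: label, float and datapath
#'   predictions, agree flag, max absolute score deviation).
#' @export
compare_against_reference <- function(dataset, w, fmt = fixed_point_format(),
                                      split = "test") {
  stopifnot(inherits(dataset, "beat_dataset"))
  validate_model_weights(w)
  keep <- dataset_rows(dataset, split)
  X <- dataset$x[keep, , drop = FALSE]
  y <- dataset$y[keep]
  n <- nrow(X)
  if (n == 0L) stop("no beats in the requested split")
  qw <- quantize_weights(w, fmt)
  S_float <- nn_forward_batch(X, w)$S
  pred_float <- BEAT_CLASSES[max.col(S_float, ties.method = "first")]
  pred_dp <- character(n)
  dev <- numeric(n)
  for (i in seq_len(n)) {
    xt <- matrix(X[i, ], 2L, 24L, byrow = TRUE)
    res <- run_inference(qtensor(xt, fmt), qw)
    pred_dp[i] <- res$predicted
    dev[i] <- max(abs(res$scores - S_float[i, ]))
  }
  agree <- pred_dp == pred_float
  structure(list(
    agreement = mean(agree),
    max_abs_score_dev = max(dev),
    n = n,
    fmt = fmt,
    per_beat = data.frame(label = y, float_pred = pred_float,
                          datapath_pred = pred_dp, agree = agree,
                          max_score_dev = dev, stringsAsFactors = FALSE)
  ), class = "datapath_report")
}

#' @export
print.datapath_report <- function(x, ...) {
  cat(sprintf("<datapath_report> %d beats, Q%d.%d\n", x$n,
              x$fmt$total_bits - x$fmt$frac_bits, x$fmt$frac_bits))
  cat(sprintf("  class agreement: %.2f%%   max |score deviation|: %.3g\n",
              100 * x$agreement, x$max_abs_score_dev))
  invisible(x)
}

#' Write a per-beat comparison report as delimited text
#'
#' @param report A `datapath_report`.
#' @param path Output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_datapath_report <- function(report, path) {
  stopifnot(inherits(report, "datapath_report"))
  utils::write.table(report$per_beat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
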