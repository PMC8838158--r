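#' Calibrate weights for fixed-point deployment
#'
#' A network trained in floating point routinely produces intermediate
#' activations far outside the range representable by the datapath's
#' activation format (about +/-8 at the default Q4.12), which saturates
#' the units and destroys the prediction.  Because the network has no
#' bias terms, its scores are multilinear in the five weight groups and
#' ReLU/max-pooling commute with positive scaling: multiplying any group
#' by a > 0 multiplies every downstream activation and all six scores by
#' a and leaves the argmax -- the only thing inference uses -- intact.
#'
#' This routine measures the per-stage activation maxima on a
#' calibration split (falling back to analytic worst-case bounds when no
#' data is given) and rescales each weight group so every requantised
#' stage stays below `1/margin` of the saturation level, and every
#' coefficient fits the weight format.  It must be applied before
#' [quantize_weights()] for faithful datapath inference.
#'
#' @param w Trained float `model_weights`.
#' @param fmt Target [fixed_point_format()].
#' @param dataset Optional `beat_dataset` used for calibration (its
#'   training split; all rows when untagged).
#' @param margin Headroom factor >= 1 between the calibrated maxima and
#'   the saturation rail (default 2: covers beats up to twice as extreme
#'   as the calibration data).
#' @return List with `weights` (rescaled `model_weights`), `scales` (the
#'   five per-group factors) and `score_scale` (their product: float
#'   scores shrink by this factor; the argmax is unchanged).
#' @export
calibrate_weights <- function(w, fmt = fixed_point_format(), dataset = NULL,
                              margin = 2) {
  validate_model_weights(w)
  stopifnot(margin >= 1)
  amax <- fmt_max_int(fmt) / 2^fmt$frac_bits
  cap <- amax / margin
  wide_cap <- (2^(fmt$acc_bits - 1L) - 1) / 2^(2L * fmt$frac_bits) / margin

  if (!is.null(dataset)) {
    rows <- dataset_rows(dataset, "train")
    if (!length(rows)) rows <- dataset_rows(dataset, "all")
    cache <- nn_forward_batch(dataset$x[rows, , drop = FALSE], w)
    m <- c(
      max(vapply(cache$A1, max, numeric(1))),
      max(cache$A2),
      max(vapply(cache$A3, max, numeric(1))),
      max(cache$H),
      max(abs(cache$S))
    )
  } else {
    # analytic worst case from kernel L1 norms, inputs in [-1, 1]
    m1 <- max(vapply(1:3, function(k) sum(abs(w$conv1[k, ])), numeric(1)))
    m2 <- sum(abs(w$conv2)) * m1
    m3 <- max(vapply(1:3, function(k) sum(abs(w$conv3[k, ])), numeric(1))) * m2
    m4 <- max(colSums(abs(w$fc1))) * m3
    m5 <- max(colSums(abs(w$fc2))) * m4
    m <- c(m1, m2, m3, m4, m5)
  }
  m <- pmax(m, .Machine$double.eps)

  groups <- c("conv1", "conv2", "conv3", "fc1", "fc2")
  caps <- c(cap, cap, cap, cap, wide_cap)
  scales <- numeric(5)
  running <- 1
  out <- w
  for (g in seq_len(5)) {
    a <- min(1, caps[g] / (m[g] * running),
             amax / max(abs(w[[groups[g]]])))
    out[[groups[g]]] <- w[[groups[g]]] * a
    scales[g] <- a
    running <- running * a
  }
  names(scales) <- groups
  list(weights = out, scales = scales, score_scale = running)
}
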