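#' Q-format fixed-point representation
#'
#' Signed two's-complement fixed point: a real x is represented by the
#' integer round(x * 2^frac_bits), saturated to
#' \[-2^(total_bits-1), 2^(total_bits-1) - 1\].  Rounding is
#' round-to-nearest with ties to even; saturation is the defined overflow
#' behaviour (no wrap-around).  The datapath's multiply-accumulate unit
#' carries products and sums in a wider accumulator (`acc_bits`) and never
#' rounds mid-accumulation; values are requantised only at unit outputs.
#'
#' Integers are stored as R doubles so that products up to 2^53 stay
#' exact; the processing element checks this bound at run time.
#'
#' @param total_bits Word length, 2..32 (default 16).
#' @param frac_bits Fractional bits, 0 <= frac_bits < total_bits
#'   (default 12).
#' @param acc_bits Accumulator width for wide sums (default 32).
#' @return An object of class `fixed_point_format`.
#' @examples
#' fmt <- fixed_point_format(16, 12)
#' quantize(0.5, fmt)       # 2048
#' dequantize(2048, fmt)    # 0.5
#' @export
fixed_point_format <- function(total_bits = 16L, frac_bits = 12L,
                               acc_bits = 32L) {
  total_bits <- as.integer(total_bits)
  frac_bits <- as.integer(frac_bits)
  acc_bits <- as.integer(acc_bits)
  if (total_bits < 2L || total_bits > 32L) stop("total_bits must be in 2..32")
  if (frac_bits < 0L || frac_bits >= total_bits) {
    stop("frac_bits must satisfy 0 <= frac_bits < total_bits")
  }
  if (acc_bits < total_bits || acc_bits > 52L) {
    stop("acc_bits must be in [total_bits, 52]")
  }
  structure(list(total_bits = total_bits, frac_bits = frac_bits,
                 acc_bits = acc_bits),
            class = "fixed_point_format")
}

#' @export
print.fixed_point_format <- function(x, ...) {
  cat(sprintf("<fixed_point_format> Q%d.%d signed (%d-bit word, %d-bit accumulator)\n",
              x$total_bits - x$frac_bits, x$frac_bits, x$total_bits, x$acc_bits))
  invisible(x)
}

fmt_max_int <- function(fmt) 2^(fmt$total_bits - 1L) - 1
fmt_min_int <- function(fmt) -2^(fmt$total_bits - 1L)

#' Quantize reals to fixed-point integers
#'
#' @param x Numeric vector, matrix or array.
#' @param fmt A [fixed_point_format()].
#' @return Same shape as `x`, holding the representation integers
#'   (as doubles).
#' @export
quantize <- function(x, fmt) {
  v <- round(x * 2^fmt$frac_bits)  # round() is ties-to-even
  v[v > fmt_max_int(fmt)] <- fmt_max_int(fmt)
  v[v < fmt_min_int(fmt)] <- fmt_min_int(fmt)
  v
}

#' @rdname quantize
#' @param v Integer representation (as produced by `quantize()`).
#' @export
dequantize <- function(v, fmt) {
  v / 2^fmt$frac_bits
}

#' Wrap a quantized tensor with its format
#'
#' @param x Real-valued tensor to quantize, or (with `already_integer =
#'   TRUE`) a tensor of representation integers.
#' @param fmt A [fixed_point_format()].
#' @param already_integer Set when `x` already holds representation
#'   integers.
#' @return An object of class `qtensor` with elements `integers` and `fmt`.
#' @export
qtensor <- function(x, fmt, already_integer = FALSE) {
  ints <- if (already_integer) x else quantize(x, fmt)
  if (any(ints > fmt_max_int(fmt)) || any(ints < fmt_min_int(fmt))) {
    stop("integers exceed the representable range of the format")
  }
  if (any(ints != round(ints))) stop("qtensor integers must be whole numbers")
  structure(list(integers = ints, fmt = fmt), class = "qtensor")
}

#' @export
print.qtensor <- function(x, ...) {
  d <- dim(x$integers)
  cat(sprintf("<qtensor> %s, Q%d.%d\n",
              if (is.null(d)) sprintf("length %d", length(x$integers))
              else paste(d, collapse = "x"),
              x$fmt$total_bits - x$fmt$frac_bits, x$fmt$frac_bits))
  invisible(x)
}

# Arithmetic right shift with round-to-nearest-even, then saturation to
# fmt.  Used to requantise wide Q(2f) accumulator values to Q(f) at unit
# outputs.  v must hold exact integers.
rshift_round_even <- function(v, bits, fmt = NULL) {
  if (bits == 0L) {
    q <- v
  } else {
    s <- 2^bits
    q0 <- floor(v / s)
    r <- v - q0 * s
    half <- s / 2
    up <- (r > half) | (r == half & (q0 %% 2 == 1))
    q <- q0 + up
  }
  if (!is.null(fmt)) {
    q[q > fmt_max_int(fmt)] <- fmt_max_int(fmt)
    q[q < fmt_min_int(fmt)] <- fmt_min_int(fmt)
  }
  q
}

#' Quantize a trained weight set
#'
#' Elementwise [quantize()] of all five weight groups; the 297-count
#' invariant is preserved.
#'
#' @param w A `model_weights` object.
#' @param fmt A [fixed_point_format()].
#' @return An object of class `q_model_weights`: the five integer groups
#'   plus `fmt`.
#' @export
quantize_weights <- function(w, fmt = fixed_point_format()) {
  validate_model_weights(w)
  qw <- list(
    conv1 = quantize(w$conv1, fmt),
    conv2 = quantize(w$conv2, fmt),
    conv3 = quantize(w$conv3, fmt),
    fc1 = quantize(w$fc1, fmt),
    fc2 = quantize(w$fc2, fmt),
    fmt = fmt
  )
  class(qw) <- "q_model_weights"
  qw
}

#' Dequantize a quantized weight set back to floats
#'
#' @param qw A `q_model_weights` object.
#' @return A `model_weights` object with values `integers / 2^frac_bits`.
#' @export
dequantize_weights <- function(qw) {
  stopifnot(inherits(qw, "q_model_weights"))
  f <- qw$fmt
  model_weights(
    conv1 = dequantize(qw$conv1, f),
    conv2 = dequantize(qw$conv2, f),
    conv3 = dequantize(qw$conv3, f),
    fc1 = dequantize(qw$fc1, f),
    fc2 = dequantize(qw$fc2, f)
  )
}

#' @export
print.q_model_weights <- function(x, ...) {
  cat(sprintf("<q_model_weights> 297 integers, Q%d.%d\n",
              x$fmt$total_bits - x$fmt$frac_bits, x$fmt$frac_bits))
  invisible(x)
}
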