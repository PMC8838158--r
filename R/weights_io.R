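#' Save and load weight files
#'
#' Weights are stored as JSON with named groups (`conv1`, `conv2`,
#' `conv3`, `fc1`, `fc2`), a `format_version` field and a `type` field
#' (`"float"` or `"fixed_point"`).  Quantized files additionally carry
#' the fixed-point format and store the representation integers exactly.
#' Loading validates the 297-parameter invariant.
#'
#' @param w A `model_weights` or `q_model_weights` object.
#' @param path File path (conventionally `.json`).
#' @return `save_weights()` returns `path` invisibly; `load_weights()`
#'   returns a `model_weights` or `q_model_weights` according to the
#'   file's `type`.
#' @export
save_weights <- function(w, path) {
  if (inherits(w, "model_weights")) {
    validate_model_weights(w)
    obj <- list(format_version = 1L, type = "float",
                conv1 = w$conv1, conv2 = w$conv2, conv3 = w$conv3,
                fc1 = w$fc1, fc2 = w$fc2)
  } else if (inherits(w, "q_model_weights")) {
    obj <- list(format_version = 1L, type = "fixed_point",
                total_bits = w$fmt$total_bits, frac_bits = w$fmt$frac_bits,
                acc_bits = w$fmt$acc_bits,
                conv1 = w$conv1, conv2 = w$conv2, conv3 = w$conv3,
                fc1 = w$fc1, fc2 = w$fc2)
  } else {
    stop("w must be a model_weights or q_model_weights object")
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1L) {
    stop("unsupported weight file version: ",
         if (is.null(obj$format_version)) "missing" else obj$format_version)
  }
  need <- c("conv1", "conv2", "conv3", "fc1", "fc2")
  if (!all(need %in% names(obj))) {
    stop("weight file is missing groups: ",
         paste(setdiff(need, names(obj)), collapse = ", "))
  }
  total <- sum(vapply(obj[need], length, integer(1)))
  if (total != 297L) {
    stop("weight file violates the 297-parameter invariant (found ", total, ")")
  }
  if (identical(obj$type, "fixed_point")) {
    fmt <- fixed_point_format(obj$total_bits, obj$frac_bits,
                              if (is.null(obj$acc_bits)) 32L else obj$acc_bits)
    qw <- list(conv1 = matrix(as.numeric(obj$conv1), 3, 7),
               conv2 = as.numeric(obj$conv2),
               conv3 = matrix(as.numeric(obj$conv3), 3, 7),
               fc1 = matrix(as.numeric(obj$fc1), 6, 21),
               fc2 = matrix(as.numeric(obj$fc2), 21, 6),
               fmt = fmt)
    class(qw) <- "q_model_weights"
    qw
  } else {
    model_weights(conv1 = matrix(as.numeric(obj$conv1), 3, 7),
                  conv2 = as.numeric(obj$conv2),
                  conv3 = matrix(as.numeric(obj$conv3), 3, 7),
                  fc1 = matrix(as.numeric(obj$fc1), 6, 21),
                  fc2 = matrix(as.numeric(obj$fc2), 21, 6))
  }
}
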