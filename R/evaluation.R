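#' @title Confusion-matrix evaluation
#' @description Standard reporting for the six-class task: a 6x6
#'   confusion matrix (rows = labelled class, columns = predicted
#'   class), per-class recall (the diagonal entry over its row sum,
#'   printed as a whole percent) and overall accuracy (trace over
#'   total).
#' @name evaluation
NULL

#' Confusion matrix of labels vs. predictions
#'
#' @param labels Character vector of true class codes.
#' @param predictions Character vector of predicted class codes, same
#'   length.
#' @return 6x6 integer matrix with dimnames in [BEAT_CLASSES] order;
#'   entry (i, j) counts beats labelled class i and predicted class j.
#' @export
confusion_matrix <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop("labels and predictions must have equal length")
  }
  lf <- factor(labels, levels = BEAT_CLASSES)
  pf <- factor(predictions, levels = BEAT_CLASSES)
  if (anyNA(lf) || anyNA(pf)) stop("invalid beat class codes")
  cm <- table(label = lf, predicted = pf)
  matrix(as.integer(cm), 6L, 6L,
         dimnames = list(label = BEAT_CLASSES, predicted = BEAT_CLASSES))
}

#' Per-class recall
#'
#' recall\[i\] = counts\[i, i\] / rowsum\[i\].  The percent form rounds
#' half up to a whole percent (the convention under which the published
#' reference table's percent row follows from its counts).
#'
#' @param cm 6x6 confusion matrix (labels in rows).
#' @return List with `recall` (6 fractions, named by class) and
#'   `percent` (integer percents).
#' @export
per_class_recall <- function(cm) {
  cm <- as.matrix(cm)
  if (!identical(dim(cm), c(6L, 6L))) stop("confusion matrix must be 6x6")
  rs <- rowSums(cm)
  if (any(rs == 0)) {
    stop("undefined recall: class(es) with zero labelled beats: ",
         paste(BEAT_CLASSES[rs == 0], collapse = ", "))
  }
  r <- diag(cm) / rs
  names(r) <- BEAT_CLASSES
  list(recall = r, percent = as.integer(floor(100 * r + 0.5)))
}

#' Overall accuracy
#'
#' @param cm 6x6 confusion matrix.
#' @return trace(cm) / sum(cm).
#' @export
overall_accuracy <- function(cm) {
  cm <- as.matrix(cm)
  if (!identical(dim(cm), c(6L, 6L))) stop("confusion matrix must be 6x6")
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix")
  sum(diag(cm)) / tot
}

#' Evaluate a model on a dataset split
#'
#' Predicts every beat of the chosen split -- with the float network
#' ([forward()]) or, when `qw` is given, with the simulated fixed-point
#' datapath ([run_inference()]) -- and assembles the evaluation report.
#'
#' @param dataset A `beat_dataset`.
#' @param w Float `model_weights` (ignored when `qw` is given).
#' @param qw Optional `q_model_weights`; selects the datapath route.
#' @param split `"test"` (default), `"train"` or `"all"`.
#' @return List of class `eval_report`: `matrix` (confusion matrix),
#'   `recall`, `recall_percent`, `accuracy`, `n`, `route`.
#' @export
evaluate_model <- function(dataset, w = NULL, qw = NULL, split = "test") {
  stopifnot(inherits(dataset, "beat_dataset"))
  keep <- dataset_rows(dataset, split)
  if (!length(keep)) stop("no beats in the requested split")
  X <- dataset$x[keep, , drop = FALSE]
  y <- dataset$y[keep]
  if (!is.null(qw)) {
    stopifnot(inherits(qw, "q_model_weights"))
    pred <- vapply(seq_len(nrow(X)), function(i) {
      run_inference(qtensor(matrix(X[i, ], 2L, 24L, byrow = TRUE), qw$fmt),
                    qw)$predicted
    }, character(1))
    route <- "fixed_point_datapath"
  } else {
    validate_model_weights(w)
    pred <- predict_batch(X, w)
    route <- "float_reference"
  }
  cm <- confusion_matrix(y, pred)
  pr <- per_class_recall(cm)
  structure(list(matrix = cm, recall = pr$recall,
                 recall_percent = pr$percent,
                 accuracy = overall_accuracy(cm), n = length(y),
                 route = route),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d beats via %s\n", x$n, x$route))
  print(x$matrix)
  cat("per-class recall (%):",
      paste(sprintf("%s=%d", BEAT_CLASSES, x$recall_percent), collapse = "  "),
      "\n")
  cat(sprintf("overall accuracy: %.2f%%\n", 100 * x$accuracy))
  invisible(x)
}

#' Write an evaluation report as delimited text
#'
#' @param report An `eval_report`.
#' @param path Output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  con <- file(path, "w")
  on.exit(close(con))
  m <- matrix(report$matrix, 6, 6)
  tab <- data.frame(label = BEAT_CLASSES, m)
  names(tab) <- c("label", BEAT_CLASSES)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("# recall_percent\t%s",
                     paste(report$recall_percent, collapse = "\t")), con)
  writeLines(sprintf("# overall_accuracy\t%.6f", report$accuracy), con)
  invisible(path)
}

#' Reference confusion matrix shipped with the package
#'
#' Loads the published 3000-beat (500 per class) reference confusion
#' matrix stored under `inst/extdata/`; used by the validation suite to
#' check the recall/accuracy arithmetic against printed values.
#'
#' @return 6x6 integer matrix.
#' @export
reference_confusion_matrix <- function() {
  path <- system.file("extdata", "chip_confusion_reference.tsv",
                      package = "ecgcnn", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, comment.char = "#")
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(label = BEAT_CLASSES, predicted = BEAT_CLASSES)
  m
}
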