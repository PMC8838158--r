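#' @title Training
#' @description The deployed classifier only ever runs inference; its
#'   297 weights are learned offline here by mini-batch stochastic
#'   gradient descent with momentum on the softmax cross-entropy loss,
#'   with gradients obtained by backpropagation through the five layer
#'   primitives.  The softmax exponential exists only at training time;
#'   the datapath reduces it to an argmax.
#' @name training
NULL

#' Softmax probabilities
#'
#' Numerically stable: shifts by the maximum before exponentiating.
#'
#' @param z Numeric vector of raw scores.
#' @return Probability vector of the same length, summing to 1.
#' @export
softmax_prob <- function(z) {
  if (!all(is.finite(z))) stop("softmax input must be finite")
  e <- exp(z - max(z))
  e / sum(e)
}

#' Training configuration
#'
#' @param learning_rate Step size for SGD (default 0.01).
#' @param epochs Number of passes over the training split (default 100).
#' @param batch_size Mini-batch size (default 64).
#' @param momentum Classical momentum coefficient (default 0.9).
#' @param seed Mandatory RNG seed controlling initialisation and
#'   shuffling (default 1234).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, epochs = 100L,
                         batch_size = 64L, momentum = 0.9, seed = 1234L) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1,
            momentum >= 0, momentum < 1, is.numeric(seed), length(seed) == 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train the beat classifier
#'
#' Minimises mean softmax cross-entropy over the training split by
#' mini-batch gradient descent with momentum.  Bit-reproducible for a
#' given configuration seed.  Aborts with a diagnostic if the loss
#' becomes non-finite.
#'
#' @param dataset A `beat_dataset`; rows tagged `split == "train"` are
#'   used for fitting (all rows when no train tag exists), rows tagged
#'   `"test"` for the validation accuracy in the report.
#' @param config A [train_config()].
#' @param init Optional `model_weights` to start from; default Glorot
#'   initialisation seeded from `config$seed`.
#' @return List with `weights` (a `model_weights`) and `report` (class
#'   `train_report`: per-epoch mean loss, final train/validation
#'   accuracy, the config).
#' @export
train <- function(dataset, config = train_config(), init = NULL) {
  stopifnot(inherits(dataset, "beat_dataset"), inherits(config, "train_config"))
  tr <- dataset_rows(dataset, "train")
  if (length(tr) == 0L) tr <- dataset_rows(dataset, "all")
  X <- dataset$x[tr, , drop = FALSE]
  yi <- beat_class_index(dataset$y[tr]) + 1L
  if (length(unique(yi)) < 2L) stop("training needs at least 2 classes")

  w <- if (is.null(init)) init_model_weights(config$seed) else init
  validate_model_weights(w)
  groups <- c("conv1", "conv2", "conv3", "fc1", "fc2")
  vel <- lapply(w[groups], function(g) g * 0)
  names(vel) <- groups
  n <- nrow(X)
  losses <- numeric(config$epochs)

  with_preserved_rng({
    set.seed(config$seed + 1L)   # distinct stream from the initialiser
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        lg <- nn_loss_grad(X[idx, , drop = FALSE], yi[idx], w)
        if (!is.finite(lg$loss)) {
          stop(sprintf(
            "training diverged: non-finite loss at epoch %d (lr = %g); lower the learning rate",
            ep, config$learning_rate))
        }
        for (g in groups) {
          vel[[g]] <- config$momentum * vel[[g]] -
            config$learning_rate * lg$grads[[g]]
          w[[g]] <- w[[g]] + vel[[g]]
        }
        ep_loss <- ep_loss + lg$loss * length(idx)
      }
      losses[ep] <- ep_loss / n
    }
  })

  train_acc <- mean(predict_batch(X, w) == dataset$y[tr])
  te <- dataset_rows(dataset, "test")
  val_acc <- if (length(te)) {
    mean(predict_batch(dataset$x[te, , drop = FALSE], w) == dataset$y[te])
  } else NA_real_
  report <- structure(list(loss = losses, train_accuracy = train_acc,
                           val_accuracy = val_acc, config = config),
                      class = "train_report")
  list(weights = w, report = report)
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf("<train_report> %d epochs, final loss %.4f\n",
              length(x$loss), x$loss[length(x$loss)]))
  cat(sprintf("  train accuracy: %.2f%%   validation accuracy: %s\n",
              100 * x$train_accuracy,
              if (is.na(x$val_accuracy)) "n/a"
              else sprintf("%.2f%%", 100 * x$val_accuracy)))
  invisible(x)
}

#' Write a training report as delimited text
#'
#' @param report A `train_report`.
#' @param path Output file path (tab-separated; per-epoch losses plus a
#'   trailing summary comment).
#' @return `path`, invisibly.
#' @export
write_train_report <- function(report, path) {
  stopifnot(inherits(report, "train_report"))
  df <- data.frame(epoch = seq_along(report$loss), loss = report$loss)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("# train_accuracy\t%.6f\n# val_accuracy\t%.6f\n",
              report$train_accuracy, report$val_accuracy),
      file = path, append = TRUE)
  invisible(path)
}

# Gradients of the full loss for an explicit batch -- exposed for the
# finite-difference verification in the test suite.
loss_and_gradients <- function(X, y_codes, w) {
  nn_loss_grad(X, beat_class_index(y_codes) + 1L, w)
}
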