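#' @title Synthetic six-class ECG beat generator
#' @description Gaussian-sum beat model: each beat is a sum of Gaussian
#'   bumps (P, Q, R, S, T and class-specific extras such as a pacing
#'   spike or an R' notch) sampled at 360 Hz over a 48-sample window
#'   centred on the R peak, with per-beat parameter jitter and additive
#'   white noise.  The six class morphologies are caricatures sufficient
#'   to exercise a classifier -- mutually distinguishable, with the
#'   hallmark features exaggerated and compressed into the short window
#'   -- not clinical simulations.
#' @name synthetic_ecg
NULL

#' Generator configuration
#'
#' @param sampling_rate Sampling frequency in Hz; fixed at 360 (the
#'   native rate of the ambulatory recordings the classifier targets).
#' @param window Samples per beat window; fixed at 48 (R-23 .. R+24).
#' @param noise_sigma Standard deviation of additive white Gaussian
#'   noise, in normalised units relative to the R amplitude (~1).
#' @param amp_jitter Relative (multiplicative) per-beat spread of each
#'   component amplitude.
#' @param center_jitter_ms Absolute per-beat standard deviation of each
#'   component centre, in ms.
#' @param width_jitter Relative per-beat spread of each component width.
#' @param seed Integer RNG seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(sampling_rate = 360L, window = 48L,
                             noise_sigma = 0.02, amp_jitter = 0.05,
                             center_jitter_ms = 1.5, width_jitter = 0.05,
                             seed = 1L) {
  if (sampling_rate != 360L) stop("sampling_rate is fixed at 360 Hz")
  window <- as.integer(window)
  if (window < 2L || window %% 2L != 0L) stop("window must be even and >= 2")
  stopifnot(noise_sigma >= 0, amp_jitter >= 0, center_jitter_ms >= 0,
            width_jitter >= 0)
  structure(list(sampling_rate = 360L, window = window,
                 noise_sigma = noise_sigma, amp_jitter = amp_jitter,
                 center_jitter_ms = center_jitter_ms,
                 width_jitter = width_jitter, seed = as.integer(seed)),
            class = "generator_config")
}

#' A single Gaussian wave component
#'
#' @param wave Label ("P", "Q", "R", "S", "T", "Rp" for an R' notch,
#'   "spike" for a pacing artifact, ...).
#' @param amplitude Peak amplitude in normalised units.
#' @param center_ms Centre offset from the R peak in ms.
#' @param width_ms Gaussian sigma in ms (> 0).
#' @return A one-row data frame.
#' @export
wave_component <- function(wave, amplitude, center_ms, width_ms) {
  if (width_ms <= 0) stop("wave component width must be > 0")
  data.frame(wave = wave, amplitude = amplitude, center_ms = center_ms,
             width_ms = width_ms, stringsAsFactors = FALSE)
}

#' Morphology of one beat class
#'
#' @param class Beat class code (one of [BEAT_CLASSES]).
#' @param components Data frame of [wave_component()] rows; must include
#'   an R component.
#' @return An object of class `class_morphology`.
#' @export
class_morphology <- function(class, components) {
  if (!class %in% BEAT_CLASSES) stop("unknown beat class: ", class)
  if (!"R" %in% components$wave) stop("morphology must contain an R component")
  if (any(components$width_ms <= 0)) stop("component widths must be > 0")
  structure(list(class = class, components = components),
            class = "class_morphology")
}

#' Default morphology table for the six classes
#'
#' Hand-designed caricatures.  The 48-sample window at 360 Hz spans only
#' about -64 .. +67 ms around the R peak, so the P and T waves are
#' compressed towards the QRS complex; class hallmarks are kept:
#' * `N` -- narrow QRS, upright P and T;
#' * `L` -- wide notched R (R' bump), no Q, discordant (negative) T;
#' * `R` -- rsR' pattern with a deep S between the two R peaks;
#' * `V` -- very wide, large QRS without a P wave, discordant T;
#' * `A` -- early, prominent P wave with an otherwise narrow QRS;
#' * `/` -- narrow high-slope pacing spike preceding a wide QRS.
#'
#' @return Named list of six [class_morphology()] objects, one per class
#'   in [BEAT_CLASSES] order.
#' @export
default_morphologies <- function() {
  m <- list(
    "N" = rbind(
      wave_component("P", 0.20, -48, 7),
      wave_component("Q", -0.10, -13, 3),
      wave_component("R", 1.00, 0, 4.5),
      wave_component("S", -0.22, 13, 3.5),
      wave_component("T", 0.35, 42, 11)
    ),
    "L" = rbind(
      wave_component("P", 0.15, -50, 7),
      wave_component("R", 0.85, -5, 8),
      wave_component("Rp", 0.55, 12, 7),
      wave_component("S", -0.10, 28, 5),
      wave_component("T", -0.30, 50, 9)
    ),
    "R" = rbind(
      wave_component("P", 0.18, -48, 7),
      wave_component("R", 0.55, -9, 3.5),
      wave_component("S", -0.45, 2, 3.5),
      wave_component("Rp", 0.80, 13, 5),
      wave_component("T", -0.25, 48, 9)
    ),
    "V" = rbind(
      wave_component("Q", -0.15, -20, 6),
      wave_component("R", 1.15, 2, 11),
      wave_component("S", -0.40, 24, 7),
      wave_component("T", -0.45, 52, 10)
    ),
    "A" = rbind(
      wave_component("P", 0.45, -55, 5),
      wave_component("Q", -0.08, -13, 3),
      wave_component("R", 0.90, 0, 4.5),
      wave_component("S", -0.20, 13, 3.5),
      wave_component("T", 0.28, 40, 11)
    ),
    "/" = rbind(
      wave_component("spike", 0.90, -30, 1.2),
      wave_component("R", 0.75, 5, 9),
      wave_component("S", -0.30, 26, 6),
      wave_component("T", -0.25, 50, 10)
    )
  )
  out <- lapply(BEAT_CLASSES, function(cl) class_morphology(cl, m[[cl]]))
  names(out) <- BEAT_CLASSES
  out
}

#' Render one beat waveform
#'
#' Evaluates the Gaussian sum at the 48 window samples (sample 24 is the
#' R centre; offsets R-23 .. R+24), after applying per-beat jitter to
#' amplitudes (multiplicative), centres (additive, ms) and widths
#' (multiplicative), then adds white Gaussian noise.  Consumes the
#' caller's RNG stream; seed handling happens at the dataset level.
#'
#' @param m A [class_morphology()].
#' @param cfg A [generator_config()].
#' @param jitter Apply per-beat jitter (disable for class-mean waveforms).
#' @param noise Add measurement noise.
#' @return Numeric vector of `cfg$window` samples (unnormalised).
#' @export
render_beat <- function(m, cfg = generator_config(), jitter = TRUE,
                        noise = TRUE) {
  stopifnot(inherits(m, "class_morphology"), inherits(cfg, "generator_config"))
  w <- cfg$window
  t_ms <- (seq_len(w) - w / 2) * 1000 / cfg$sampling_rate
  comp <- m$components
  a <- comp$amplitude
  mu <- comp$center_ms
  sg <- comp$width_ms
  if (jitter) {
    k <- nrow(comp)
    a <- a * (1 + cfg$amp_jitter * stats::rnorm(k))
    mu <- mu + cfg$center_jitter_ms * stats::rnorm(k)
    sg <- pmax(sg * (1 + cfg$width_jitter * stats::rnorm(k)), 0.3)
  }
  s <- numeric(w)
  for (i in seq_along(a)) {
    s <- s + a[i] * exp(-(t_ms - mu[i])^2 / (2 * sg[i]^2))
  }
  if (noise && cfg$noise_sigma > 0) {
    s <- s + stats::rnorm(w, 0, cfg$noise_sigma)
  }
  s
}

#' Preprocess a raw beat window into the network input tensor
#'
#' Amplitude-normalises the window to \[-1, 1\] (division by the maximum
#' absolute value; an all-zero window stays zero) and reshapes it
#' row-major into 2 rows x 24 columns: row 1 holds samples 1..24, row 2
#' samples 25..48.  This input formation is a package convention, chosen
#' so the post-pooling feature map has the canonical 2x9 shape.
#'
#' @param samples Numeric vector of 48 samples.
#' @return 2x24 numeric matrix.
#' @export
preprocess_beat <- function(samples) {
  if (length(samples) != 48L) stop("a beat window must hold 48 samples")
  if (!all(is.finite(samples))) stop("beat samples must be finite")
  m <- max(abs(samples))
  if (m > 0) samples <- samples / m
  matrix(samples, 2L, 24L, byrow = TRUE)
}

#' Generate a labelled synthetic dataset
#'
#' Renders `n_train_per_class + n_test_per_class` beats for each of the
#' six classes, preprocesses them and tags train/test splits.  Fully
#' deterministic given `cfg$seed`.  The defaults (2000 train + 500 test
#' per class, 15,000 beats total) match the standard benchmark split
#' size for this classifier.
#'
#' @param n_train_per_class,n_test_per_class Beats per class and split.
#' @param cfg A [generator_config()].
#' @param morphologies Morphology table (default [default_morphologies()]).
#' @return An object of class `beat_dataset`: list with `x` (n x 48
#'   matrix of normalised samples, row-major tensor layout), `y`
#'   (character class codes), `split` ("train"/"test") and `cfg`.
#' @export
generate_dataset <- function(n_train_per_class = 2000L,
                             n_test_per_class = 500L,
                             cfg = generator_config(),
                             morphologies = default_morphologies()) {
  stopifnot(n_train_per_class >= 1L, n_test_per_class >= 1L)
  n_per <- n_train_per_class + n_test_per_class
  n <- 6L * n_per
  X <- matrix(0, n, 48L)
  y <- character(n)
  split <- character(n)
  with_preserved_rng({
    set.seed(cfg$seed)
    row <- 1L
    for (cl in BEAT_CLASSES) {
      m <- morphologies[[cl]]
      for (i in seq_len(n_per)) {
        beat <- render_beat(m, cfg)
        X[row, ] <- as.vector(t(preprocess_beat(beat)))
        y[row] <- cl
        split[row] <- if (i <= n_train_per_class) "train" else "test"
        row <- row + 1L
      }
    }
  })
  structure(list(x = X, y = y, split = split, cfg = cfg),
            class = "beat_dataset")
}

#' @export
print.beat_dataset <- function(x, ...) {
  cat(sprintf("<beat_dataset> %d beats (%d train / %d test), %d classes\n",
              nrow(x$x), sum(x$split == "train"), sum(x$split == "test"),
              length(unique(x$y))))
  print(table(class = x$y, split = x$split))
  invisible(x)
}

# Row selector shared by evaluation and comparison code.
dataset_rows <- function(dataset, split = "all") {
  if (split == "all") seq_len(nrow(dataset$x)) else which(dataset$split == split)
}

#' Extract one beat of a dataset as a 2x24 tensor
#'
#' @param dataset A `beat_dataset`.
#' @param i Row index.
#' @return 2x24 numeric matrix.
#' @export
dataset_tensor <- function(dataset, i) {
  matrix(dataset$x[i, ], 2L, 24L, byrow = TRUE)
}

#' Nearest-class-mean baseline accuracy
#'
#' Classifies each test beat by the closest (L2) class-mean training
#' waveform.  A cheap sanity oracle: if this scores near chance the
#' generator gives the network nothing to learn.
#'
#' @param dataset A `beat_dataset` with both splits.
#' @return Fraction of test beats assigned to their true class.
#' @export
nearest_mean_accuracy <- function(dataset) {
  tr <- dataset_rows(dataset, "train")
  te <- dataset_rows(dataset, "test")
  means <- vapply(BEAT_CLASSES, function(cl) {
    colMeans(dataset$x[tr[dataset$y[tr] == cl], , drop = FALSE])
  }, numeric(ncol(dataset$x)))
  Xte <- dataset$x[te, , drop = FALSE]
  d2 <- vapply(seq_len(ncol(means)), function(k) {
    rowSums(sweep(Xte, 2L, means[, k])^2)
  }, numeric(nrow(Xte)))
  pred <- BEAT_CLASSES[max.col(-d2, ties.method = "first")]
  mean(pred == dataset$y[te])
}

#' Width of the R complex at half maximum
#'
#' Measures, on a rendered waveform, the width (ms) of the region around
#' the global maximum that stays above half of it.  Used to verify that
#' wide-QRS classes (e.g. PVC) render wider complexes than normal beats.
#'
#' @param samples Beat waveform (48 samples).
#' @param sampling_rate Hz.
#' @return Width in ms.
#' @export
halfmax_width_ms <- function(samples, sampling_rate = 360) {
  p <- which.max(samples)
  half <- samples[p] / 2
  lo <- p
  while (lo > 1L && samples[lo - 1L] >= half) lo <- lo - 1L
  hi <- p
  while (hi < length(samples) && samples[hi + 1L] >= half) hi <- hi + 1L
  (hi - lo + 1L) * 1000 / sampling_rate
}

#' Write / read a beat dataset as tab-separated text
#'
#' One row per beat: the 48 normalised samples (`s1`..`s48`, tensor
#' row-major order), the class code and the split tag.
#'
#' @param dataset A `beat_dataset`.
#' @param path File path.
#' @return `write_beat_dataset()` returns `path` invisibly;
#'   `read_beat_dataset()` returns a `beat_dataset`.
#' @export
write_beat_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "beat_dataset"))
  df <- as.data.frame(dataset$x)
  names(df) <- paste0("s", seq_len(ncol(df)))
  df$class <- dataset$y
  df$split <- dataset$split
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beat_dataset
#' @export
read_beat_dataset <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  scols <- paste0("s", 1:48)
  if (!all(scols %in% names(df)) || !all(c("class", "split") %in% names(df))) {
    stop("not a beat dataset file: expected columns s1..s48, class, split")
  }
  bad <- setdiff(unique(df$class), BEAT_CLASSES)
  if (length(bad)) stop("unknown class codes in file: ", paste(bad, collapse = ", "))
  structure(list(x = as.matrix(df[, scols]), y = df$class, split = df$split,
                 cfg = NULL),
            class = "beat_dataset")
}
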