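#' @title Minimal WFDB reader/writer
#' @description Just enough of the WFDB conventions to segment beats
#'   from MIT-BIH style records without external dependencies: header
#'   (`.hea`) parsing, signal formats 212 (packed 12-bit pairs) and 16
#'   (little-endian int16), and the standard binary annotation format
#'   (6-bit type code + 10-bit time increment words, with SKIP/AUX/NUM/
#'   SUB/CHN escapes).  Writers exist so the test suite can build
#'   fixtures in code; they are not a general-purpose exporter.
#' @name wfdb
NULL

# Annotation type code -> display symbol (subset of the standard table).
WFDB_ANN_SYMBOLS <- c(
  "1" = "N", "2" = "L", "3" = "R", "4" = "a", "5" = "V", "6" = "F",
  "7" = "J", "8" = "A", "9" = "S", "10" = "E", "11" = "j", "12" = "/",
  "13" = "Q", "14" = "~", "16" = "|", "22" = "\"", "24" = "p",
  "25" = "B", "26" = "^", "27" = "t", "28" = "+", "30" = "?",
  "31" = "!", "34" = "e", "35" = "f", "38" = "x"
)

wfdb_symbol_for_code <- function(code) {
  s <- WFDB_ANN_SYMBOLS[as.character(code)]
  s[is.na(s)] <- "?"
  unname(s)
}

#' Read a WFDB header
#'
#' @param hea_path Path to the `.hea` file.
#' @return List with `record`, `n_sig`, `fs`, `n_samples` and `signals`
#'   (data frame: file, format, gain, baseline, description).
#' @export
read_wfdb_header <- function(hea_path) {
  if (!file.exists(hea_path)) stop("cannot read WFDB header: ", hea_path)
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty WFDB header: ", hea_path)
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(top) < 4L) stop("malformed WFDB record line in ", hea_path)
  n_sig <- as.integer(top[2L])
  fs <- as.numeric(top[3L])
  n_samples <- as.integer(top[4L])
  if (length(lines) < 1L + n_sig) stop("header lists fewer signal lines than n_sig")
  sig <- lapply(lines[1L + seq_len(n_sig)], function(ln) {
    tk <- strsplit(trimws(ln), "\\s+")[[1L]]
    fmt <- as.integer(sub("[x:+].*$", "", tk[2L]))
    gain_tok <- if (length(tk) >= 3L) tk[3L] else "200"
    gain <- as.numeric(sub("[(/].*$", "", gain_tok))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gain_tok)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_tok))
    } else if (length(tk) >= 5L) {
      as.numeric(tk[5L])   # adczero fallback
    } else 0
    desc <- if (length(tk) >= 9L) paste(tk[9:length(tk)], collapse = " ") else ""
    data.frame(file = tk[1L], format = fmt, gain = gain,
               baseline = baseline, description = desc,
               stringsAsFactors = FALSE)
  })
  list(record = sub("/.*$", "", top[1L]), n_sig = n_sig, fs = fs,
       n_samples = n_samples, signals = do.call(rbind, sig))
}

#' Read WFDB signals
#'
#' Supports formats 212 and 16; all signals of a record must share one
#' signal file (the MIT-BIH layout).
#'
#' @param hea_path Path to the `.hea` file; the signal file is resolved
#'   relative to it.
#' @return List with `header` and `adc`: an `n_samples` x `n_sig` matrix
#'   of raw ADC integers.
#' @export
read_wfdb_signals <- function(hea_path) {
  hdr <- read_wfdb_header(hea_path)
  sig_file <- unique(hdr$signals$file)
  fmt <- unique(hdr$signals$format)
  if (length(sig_file) != 1L || length(fmt) != 1L) {
    stop("only single-file, single-format records are supported")
  }
  dat_path <- file.path(dirname(hea_path), sig_file)
  if (!file.exists(dat_path)) stop("cannot read signal file: ", dat_path)
  raw <- readBin(dat_path, "raw", file.size(dat_path))
  n_flat <- hdr$n_samples * hdr$n_sig
  if (fmt == 212L) {
    vals <- decode_fmt212(raw, n_flat)
  } else if (fmt == 16L) {
    b <- as.integer(raw)
    if (length(b) < 2L * n_flat) stop("signal file truncated")
    lo <- b[seq(1L, 2L * n_flat, by = 2L)]
    hi <- b[seq(2L, 2L * n_flat, by = 2L)]
    vals <- lo + 256L * hi
    vals[vals >= 32768L] <- vals[vals >= 32768L] - 65536L
  } else {
    stop("unsupported WFDB signal format: ", fmt)
  }
  adc <- matrix(vals, ncol = hdr$n_sig, byrow = TRUE)
  list(header = hdr, adc = adc)
}

decode_fmt212 <- function(raw, n_flat) {
  n_pairs <- ceiling(n_flat / 2)
  if (length(raw) < 3L * n_pairs) stop("signal file truncated")
  b <- as.integer(raw)
  i0 <- 3L * (seq_len(n_pairs) - 1L)
  s1 <- b[i0 + 1L] + 256L * (b[i0 + 2L] %% 16L)
  s2 <- b[i0 + 3L] + 256L * (b[i0 + 2L] %/% 16L)
  v <- as.vector(rbind(s1, s2))[seq_len(n_flat)]
  v[v >= 2048L] <- v[v >= 2048L] - 4096L
  v
}

#' Read a WFDB annotation file (MIT format)
#'
#' @param ann_path Path to the annotation file (e.g. `.atr`).
#' @return Data frame with `sample` (0-based sample number), `code`
#'   (annotation type code) and `symbol`.
#' @export
read_wfdb_annotations <- function(ann_path) {
  if (!file.exists(ann_path)) stop("cannot read annotation file: ", ann_path)
  raw <- as.integer(readBin(ann_path, "raw", file.size(ann_path)))
  i <- 1L
  t <- 0
  samples <- numeric(0)
  codes <- integer(0)
  while (i + 1L <= length(raw)) {
    lo <- raw[i]; hi <- raw[i + 1L]
    i <- i + 2L
    A <- hi %/% 4L
    I <- (hi %% 4L) * 256L + lo
    if (A == 0L && I == 0L) break
    if (A == 59L) {              # SKIP: 4-byte interval, high word first
      if (I == 0L) {
        if (i + 3L > length(raw)) stop("truncated SKIP annotation")
        high <- raw[i] + 256L * raw[i + 1L]
        low <- raw[i + 2L] + 256L * raw[i + 3L]
        i <- i + 4L
        t <- t + high * 65536 + low
      }
    } else if (A == 63L) {       # AUX: I bytes of payload (+ pad to even)
      skip <- I + (I %% 2L)
      i <- i + skip
    } else if (A %in% c(60L, 61L, 62L)) {
      # NUM / SUB / CHN modifiers: no time advance, not needed here
    } else {
      t <- t + I
      samples <- c(samples, t)
      codes <- c(codes, A)
    }
  }
  data.frame(sample = samples, code = codes,
             symbol = wfdb_symbol_for_code(codes), stringsAsFactors = FALSE)
}

#' Write a WFDB record (fixture helper)
#'
#' @param adc `n_samples` x `n_sig` matrix of ADC integers.
#' @param dir Output directory.
#' @param record Record name (base of the `.hea`/`.dat` files).
#' @param fs Sampling frequency in Hz.
#' @param format Signal format, 212 or 16.
#' @param gain ADC units per physical unit.
#' @param baseline ADC value corresponding to 0 physical units.
#' @return Path to the written `.hea` file, invisibly.
#' @export
write_wfdb_record <- function(adc, dir, record, fs = 360, format = 212L,
                              gain = 200, baseline = 0) {
  adc <- as.matrix(adc)
  n <- nrow(adc); ns <- ncol(adc)
  flat <- as.vector(t(adc))
  dat <- paste0(record, ".dat")
  if (format == 212L) {
    if (any(flat < -2048 | flat > 2047)) stop("format 212 holds 12-bit samples")
    if (length(flat) %% 2L == 1L) flat <- c(flat, 0L)
    u <- ifelse(flat < 0, flat + 4096L, flat)
    s1 <- u[seq(1L, length(u), by = 2L)]
    s2 <- u[seq(2L, length(u), by = 2L)]
    bytes <- as.raw(rbind(s1 %% 256L, (s2 %/% 256L) * 16L + s1 %/% 256L,
                          s2 %% 256L))
  } else if (format == 16L) {
    if (any(flat < -32768 | flat > 32767)) stop("format 16 holds 16-bit samples")
    u <- ifelse(flat < 0, flat + 65536L, flat)
    bytes <- as.raw(rbind(u %% 256L, u %/% 256L))
  } else {
    stop("unsupported WFDB signal format: ", format)
  }
  writeBin(as.vector(bytes), file.path(dir, dat))
  hea <- c(sprintf("%s %d %g %d", record, ns, fs, n),
           vapply(seq_len(ns), function(k) {
             sprintf("%s %d %g(%g)/mV 12 0 0 0 0 sig%d",
                     dat, format, gain, baseline, k)
           }, character(1)))
  hea_path <- file.path(dir, paste0(record, ".hea"))
  writeLines(hea, hea_path)
  invisible(hea_path)
}

#' Write a WFDB annotation file (fixture helper)
#'
#' @param samples 0-based annotation sample numbers (sorted).
#' @param codes Annotation type codes (integers) or symbols (characters,
#'   mapped through the standard table).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wfdb_annotations <- function(samples, codes, path) {
  if (is.character(codes)) {
    codes <- vapply(codes, function(s) {
      k <- names(WFDB_ANN_SYMBOLS)[match(s, WFDB_ANN_SYMBOLS)]
      if (is.na(k)) stop("no annotation code for symbol: ", s)
      as.integer(k)
    }, integer(1))
  }
  stopifnot(length(samples) == length(codes), !is.unsorted(samples))
  out <- integer(0)
  t <- 0
  for (j in seq_along(samples)) {
    dt <- samples[j] - t
    t <- samples[j]
    if (dt > 1023) {             # emit SKIP with 4-byte interval
      out <- c(out, 0L, 59L * 4L,
               (dt %/% 65536) %% 256L, dt %/% 16777216,
               dt %% 256L, (dt %/% 256L) %% 256L)
      dt <- 0
    }
    out <- c(out, dt %% 256L, codes[j] * 4L + dt %/% 256L)
  }
  out <- c(out, 0L, 0L)          # EOF word
  writeBin(as.raw(out), path)
  invisible(path)
}

#' Segment labelled beats from a WFDB record
#'
#' Centres a 48-sample window (R-23 .. R+24) on every annotation whose
#' symbol is one of the six beat classes, converts ADC values to
#' physical units, preprocesses each window ([preprocess_beat()]) and
#' returns a `beat_dataset`.  Annotations with other symbols are
#' ignored; windows that would cross the record bounds are skipped and
#' counted.
#'
#' @param hea_path Path to the record's `.hea` file.
#' @param ann_path Path to the annotation file (default: the record's
#'   `.atr` next to the header).
#' @param channel Signal channel to use (default 1).
#' @param split Split tag given to the extracted beats.
#' @return A `beat_dataset` with an extra element `skipped` (number of
#'   in-class annotations dropped at the record bounds).
#' @export
extract_mitbih_beats <- function(hea_path, ann_path = NULL, channel = 1L,
                                 split = "test") {
  sig <- read_wfdb_signals(hea_path)
  if (is.null(ann_path)) {
    ann_path <- sub("\\.hea$", ".atr", hea_path)
  }
  ann <- read_wfdb_annotations(ann_path)
  hdr <- sig$header
  if (channel < 1L || channel > hdr$n_sig) stop("no such channel: ", channel)
  g <- hdr$signals$gain[channel]
  b <- hdr$signals$baseline[channel]
  x <- (sig$adc[, channel] - b) / g
  keep <- ann$symbol %in% BEAT_CLASSES
  centers <- ann$sample[keep] + 1L         # 0-based sample -> 1-based index
  labels <- ann$symbol[keep]
  n_total <- length(x)
  ok <- centers - 23L >= 1L & centers + 24L <= n_total
  skipped <- sum(!ok)
  centers <- centers[ok]
  labels <- labels[ok]
  X <- matrix(0, length(centers), 48L)
  for (j in seq_along(centers)) {
    win <- x[(centers[j] - 23L):(centers[j] + 24L)]
    X[j, ] <- as.vector(t(preprocess_beat(win)))
  }
  structure(list(x = X, y = labels,
                 split = rep(split, length(labels)), cfg = NULL,
                 skipped = skipped),
            class = "beat_dataset")
}
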