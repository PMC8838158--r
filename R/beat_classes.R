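#' The six heart-beat classes
#'
#' Annotation codes for the six beat types the classifier distinguishes, in
#' fixed order: normal (`N`), left bundle branch block (`L`), right bundle
#' branch block (`R`), premature ventricular contraction (`V`), atrial
#' premature beat (`A`) and paced beat (`/`).  Class index 0 to 5 follows
#' this order everywhere in the package; ties in argmax always resolve to
#' the lowest index.
#'
#' @format Character vector of length 6.
#' @export
BEAT_CLASSES <- c("N", "L", "R", "V", "A", "/")

#' Beat class table
#'
#' @return A data frame with columns `code` (annotation symbol), `index`
#'   (0-based class index) and `disease` (long name).
#' @examples
#' beat_classes()
#' @export
beat_classes <- function() {
  data.frame(
    code = BEAT_CLASSES,
    index = 0:5,
    disease = c(
      "Normal Beat",
      "Left Bundle Branch Block Beat (LBBB)",
      "Right Bundle Branch Block Beat (RBBB)",
      "Premature Ventricular Contraction (PVC)",
      "Atrial Premature Beat (APB)",
      "Paced Beat"
    ),
    stringsAsFactors = FALSE
  )
}

#' Convert between beat-class codes and 0-based indices
#'
#' @param code Character vector of codes from [BEAT_CLASSES].
#' @param index Integer vector of 0-based class indices.
#' @return `beat_class_index()` returns 0-based indices; `beat_class_code()`
#'   returns codes.
#' @examples
#' beat_class_index("V")   # 3
#' beat_class_code(0)      # "N"
#' @export
beat_class_index <- function(code) {
  i <- match(code, BEAT_CLASSES)
  if (anyNA(i)) {
    stop("unknown beat class code(s): ",
         paste(unique(code[is.na(i)]), collapse = ", "))
  }
  i - 1L
}

#' @rdname beat_class_index
#' @export
beat_class_code <- function(index) {
  if (any(index < 0L | index > 5L)) stop("beat class index must be in 0..5")
  BEAT_CLASSES[index + 1L]
}
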