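#' Confusion matrix for the three ingestive behaviors
#'
#' Rows are true behaviors, columns predicted, in the fixed order
#' bite, chew, chew_bite.
#'
#' @param true_labels,predicted_labels Character vectors of equal length
#'   with values in `c("bite", "chew", "chew_bite")`.
#' @return A 3x3 integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  bad <- setdiff(unique(c(true_labels, predicted_labels)), BEHAVIORS)
  if (length(bad)) {
    stop("unknown labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cm <- table(factor(true_labels, levels = BEHAVIORS),
              factor(predicted_labels, levels = BEHAVIORS))
  cm <- matrix(as.integer(cm), 3, 3,
               dimnames = list(true = BEHAVIORS, predicted = BEHAVIORS))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Row-normalized view of a confusion matrix
#'
#' Divides each row by its support, so the diagonal holds per-class
#' recall (correct classification rates). Empty rows stay zero.
#'
#' @param cm A [confusion_matrix].
#' @return A 3x3 numeric matrix with rows summing to 1 (or 0).
#' @export
normalize_confusion <- function(cm) {
  support <- rowSums(cm)
  out <- sweep(unclass(cm), 1L, pmax(support, 1L), `/`)
  out[support == 0L, ] <- 0
  out
}

#' Precision, recall, and F1 from a confusion matrix
#'
#' Computes per-class one-vs-rest true positives, false positives, and
#' false negatives from the matrix, then
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, and
#' `F1 = 2 * precision * recall / (precision + recall)`. Overall values
#' are support-weighted averages by default; macro averaging is
#' available. A class never predicted gets precision 0 with a warning
#' (likewise recall for a class with no true instances).
#'
#' @param cm A [confusion_matrix].
#' @param average `"weighted"` (default) or `"macro"` for the overall
#'   metrics.
#' @return An object of class `metrics_report` with `per_class` (a
#'   `data.frame`) and `overall` (named numeric vector).
#' @export
precision_recall_f1 <- function(cm, average = c("weighted", "macro")) {
  average <- match.arg(average)
  m <- unclass(cm)
  if (sum(m) == 0L) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0)) {
      warning(sprintf("%s undefined for class(es) %s; reported as 0", what,
                      paste(BEHAVIORS[den == 0], collapse = ", ")),
              call. = FALSE)
    }
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  support <- rowSums(m)
  w <- if (average == "weighted") support / sum(support) else rep(1 / 3, 3)
  structure(
    list(per_class = data.frame(behavior = BEHAVIORS, precision = precision,
                                recall = recall, f1 = f1, support = support,
                                row.names = NULL, stringsAsFactors = FALSE),
         overall = c(precision = sum(w * precision), recall = sum(w * recall),
                     f1 = sum(w * f1)),
         average = average),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat("<metrics_report>\n")
  print(cbind(x$per_class[1],
              round(x$per_class[2:4], digits),
              x$per_class[5]), row.names = FALSE)
  cat(sprintf("overall (%s): precision %.3f, recall %.3f, F1 %.3f\n",
              x$average, x$overall["precision"], x$overall["recall"],
              x$overall["f1"]))
  invisible(x)
}

#' Normalized processing speed
#'
#' Milliseconds of processing time spent per second of audio processed,
#' the hardware-dependent throughput figure reported alongside accuracy.
#'
#' @param total_processing_time_s Wall-clock processing time in seconds.
#' @param total_audio_duration_s Total duration of the audio processed.
#' @return Speed in ms per 1 s of audio.
#' @export
processing_speed <- function(total_processing_time_s,
                             total_audio_duration_s) {
  if (total_audio_duration_s <= 0) {
    stop("total audio duration must be > 0", call. = FALSE)
  }
  1000 * total_processing_time_s / total_audio_duration_s
}

#' Amplitude and duration descriptors of a segment
#'
#' The segment-level normalized amplitude is the peak-to-peak sample
#' range divided by 2^16 (unitless, in `[0, 1]`); duration is
#' `length / rate` in seconds. These are the acoustic features whose
#' per-behavior means parameterize the synthetic generator.
#'
#' @param segment A non-empty [audio_segment].
#' @return A list with `amplitude` and `duration`.
#' @export
segment_descriptors <- function(segment) {
  if (length(segment$samples) == 0L) {
    stop("descriptors undefined for an empty segment", call. = FALSE)
  }
  list(
    amplitude = (max(segment$samples) - min(segment$samples)) / 65536,
    duration = duration_s(segment)
  )
}
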