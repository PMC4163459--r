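#' Confusion matrix for driver/passenger classification
#'
#' `tp` counts true drivers (positives), `tn` true passengers (negatives),
#' `fp` passengers called driver, `fn` drivers called passenger.
#'
#' @param tp,fp,tn,fn Nonnegative integer counts; their total must be > 0.
#' @return Object of class `confusion_matrix`.
#' @examples
#' confusion_matrix(tp = 1029, fp = 597, tn = 3942, fn = 0)
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  # store as doubles: the MCC denominator product overflows 32-bit integers
  counts <- c(tp = as.numeric(tp), fp = as.numeric(fp),
              tn = as.numeric(tn), fn = as.numeric(fn))
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop_validation("confusion counts must be nonnegative integers")
  }
  if (sum(counts) == 0) stop_validation("confusion matrix total must be > 0")
  structure(as.list(counts), class = "confusion_matrix")
}

#' Confusion matrix from predicted and true labels
#'
#' @param predicted,truth Vectors coercible to driver/passenger factors.
#' @return A `confusion_matrix`.
#' @export
confusion_from_labels <- function(predicted, truth) {
  p <- normalize_labels(predicted)
  t <- normalize_labels(truth)
  if (length(p) != length(t)) stop_validation("predicted and truth lengths differ")
  confusion_matrix(tp = sum(p == "driver" & t == "driver"),
                   fp = sum(p == "driver" & t == "passenger"),
                   tn = sum(p == "passenger" & t == "passenger"),
                   fn = sum(p == "passenger" & t == "driver"))
}

#' Classification metrics from a confusion matrix
#'
#' Computes recall = TP/(TP+FN), precision = TP/(TP+FP),
#' accuracy = (TP+TN)/total, F-measure = 2PR/(P+R), and the Matthews
#' correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#'
#' All metrics are returned as proportions on \[0, 1\] (MCC on \[-1, 1\]);
#' percentage rendering is left to the presentation layer (see
#' [render_metrics_percent()]). A zero MCC denominator yields MCC = 0
#' (conventional limit). An undefined precision or recall (empty predicted or
#' actual positive set — a degenerate classifier) is reported as `NA`, never
#' as 0, and propagates to the F-measure.
#'
#' @param cm A [confusion_matrix()].
#' @return Named list with elements `precision`, `recall`, `accuracy`,
#'   `f_measure`, `mcc`.
#' @examples
#' metrics_from_confusion(confusion_matrix(1029, 597, 3942, 0))
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  accuracy <- (tp + tn) / (tp + tn + fp + fn)
  f_measure <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  # products as doubles: counts in the thousands overflow integer multiplication
  denom2 <- (tp + fp) * (tp + fn) * ((tn + fp) * (tn + fn))
  mcc <- if (denom2 > 0) (tp * tn - fp * fn) / sqrt(denom2) else 0
  list(precision = precision, recall = recall, accuracy = accuracy,
       f_measure = f_measure, mcc = mcc)
}

#' Render a metric bundle on the percentage scale
#'
#' Precision, recall, accuracy and F-measure are multiplied by 100 and
#' rounded; MCC stays a correlation on \[-1, 1\].
#'
#' @param metrics List from [metrics_from_confusion()].
#' @param digits Decimal places for the percentages (default 2) and for MCC
#'   (default 4).
#' @return Named numeric vector.
#' @export
render_metrics_percent <- function(metrics, digits = 2) {
  c(accuracy = round(100 * metrics$accuracy, digits),
    recall = round(100 * metrics$recall, digits),
    precision = round(100 * metrics$precision, digits),
    f_measure = round(100 * metrics$f_measure, digits),
    mcc = round(metrics$mcc, 4))
}

#' Area under the ROC curve by rank statistic
#'
#' The probability that a randomly drawn driver receives a higher score than
#' a randomly drawn passenger, with ties counted half (equivalent to the
#' Wilcoxon/Mann-Whitney statistic).
#'
#' @param scores Numeric scores, larger meaning more driver-like.
#' @param labels Driver/passenger labels.
#' @return Scalar in \[0, 1\].
#' @examples
#' roc_area(c(0.9, 0.8, 0.3, 0.1), c("driver", "driver", "passenger", "passenger"))
#' @export
roc_area <- function(scores, labels) {
  labels <- normalize_labels(labels)
  if (length(scores) != length(labels)) stop_validation("scores and labels lengths differ")
  np <- sum(labels == "driver")
  nn <- sum(labels == "passenger")
  if (np == 0L || nn == 0L) stop_validation("ROC area requires both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == "driver"]) - np * (np + 1) / 2) / (np * nn)
}
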