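#' Repeated stratified cross-validation
#'
#' Splits samples into stratified folds, trains on the complement of each
#' fold, pools the per-fold confusion counts within each repeat, computes
#' the metric bundle per repeat (plus ROC area from the pooled out-of-fold
#' driver probabilities), and reports the mean and variance of each metric
#' across repeats. Fold assignment is driven by a single seed; the same
#' seed reproduces the report bit-exactly.
#'
#' @param x Numeric sample-by-feature matrix.
#' @param labels Driver/passenger labels.
#' @param trainer A trainer object (e.g. [rotation_forest_trainer()]).
#' @param folds Number of folds (default 5); must not exceed the smaller
#'   class size.
#' @param repeats Number of repetitions (default 5).
#' @param seed Seed for fold assignment.
#' @param audit Optional environment; every feature set handed to
#'   `trainer$fit` is appended to `audit$log` (leakage/prefix auditing).
#' @return Object of class `cv_report`: `metrics` (data frame of mean and
#'   variance per metric), `per_repeat`, and the run metadata.
#' @export
cross_validate <- function(x, labels, trainer, folds = 5, repeats = 5,
                           seed = 1, audit = NULL) {
  labels <- normalize_labels(labels)
  x <- as.matrix(x)
  if (min(table(labels)) < folds) {
    stop_validation(sprintf("folds (%d) exceeds the smaller class size (%d)",
                            folds, min(table(labels))))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  metric_names <- c("precision", "recall", "accuracy", "f_measure", "mcc", "roc_area")
  per_repeat <- matrix(NA_real_, repeats, length(metric_names),
                       dimnames = list(NULL, metric_names))
  for (r in seq_len(repeats)) {
    fold_of <- integer(length(labels))
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    counts <- c(tp = 0, fp = 0, tn = 0, fn = 0)
    oof_score <- numeric(length(labels))
    for (f in seq_len(folds)) {
      test_idx <- which(fold_of == f)
      train_idx <- which(fold_of != f)
      if (!is.null(audit)) {
        audit$log <- c(audit$log, list(colnames(x)))
      }
      model <- tryCatch(trainer$fit(x[train_idx, , drop = FALSE], labels[train_idx]),
                        error = function(e) stop(sprintf(
                          "trainer '%s' failed on repeat %d fold %d: %s",
                          trainer$name, r, f, conditionMessage(e)), call. = FALSE))
      pr <- trainer$predict_proba(model, x[test_idx, , drop = FALSE])
      pred <- ifelse(pr[, "driver"] >= pr[, "passenger"], "driver", "passenger")
      cm <- confusion_from_labels(pred, labels[test_idx])
      counts <- counts + c(tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn)
      oof_score[test_idx] <- pr[, "driver"]
    }
    stopifnot(sum(counts) == length(labels))
    mets <- metrics_from_confusion(confusion_matrix(counts["tp"], counts["fp"],
                                                    counts["tn"], counts["fn"]))
    per_repeat[r, ] <- c(mets$precision, mets$recall, mets$accuracy,
                         mets$f_measure, mets$mcc, roc_area(oof_score, labels))
  }
  metrics <- data.frame(
    metric = metric_names,
    mean = apply(per_repeat, 2, mean),
    variance = apply(per_repeat, 2, function(v) if (repeats > 1) var(v) else 0),
    row.names = NULL)
  structure(list(metrics = metrics,
                 per_repeat = as.data.frame(per_repeat),
                 folds = folds, repeats = repeats, seed = seed,
                 trainer = trainer$name, n_features = ncol(x),
                 n_samples = nrow(x),
                 variance_over = "repeats"),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %s, %d features, %d-fold x %d repeats (seed %d)\n",
              x$trainer, x$n_features, x$folds, x$repeats, x$seed))
  print(x$metrics, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Mean CV accuracy of a report
#'
#' @param report A `cv_report`.
#' @return Scalar mean accuracy across repeats.
#' @export
cv_accuracy <- function(report) {
  report$metrics$mean[report$metrics$metric == "accuracy"]
}

#' Evaluate a fitted model on a held-out test set
#'
#' Predicts the test set, builds one confusion matrix, and computes the
#' metric bundle. When the feature extractor (or its PSS reducer) that
#' produced the features is supplied, the evaluation refuses to proceed if
#' any test sample id appears among the ids the reducer was fitted on — a
#' hard guard against train/test leakage.
#'
#' @param model A fitted model accepted by `predict_proba`.
#' @param test_x Test feature matrix (columns in training order).
#' @param test_labels True labels of the test samples.
#' @param extractor Optional `feature_extractor` or `pss_reducer` used to
#'   build `test_x`; enables the leakage guard via rownames of `test_x`.
#' @return Object of class `holdout_report`: `confusion`, `metrics`,
#'   `n_test`.
#' @export
evaluate_on_holdout <- function(model, test_x, test_labels, extractor = NULL) {
  test_labels <- normalize_labels(test_labels)
  if (nrow(test_x) == 0L) stop_validation("empty test set")
  if (!is.null(extractor)) {
    fitted_ids <- if (inherits(extractor, "feature_extractor")) {
      extractor$reducer$fitted_ids
    } else if (inherits(extractor, "pss_reducer")) {
      extractor$fitted_ids
    } else {
      stop_validation("extractor must be a feature_extractor or pss_reducer")
    }
    leaked <- intersect(rownames(test_x), fitted_ids)
    if (length(leaked) > 0L) {
      stop_validation(sprintf(
        "leakage guard: %d test sample(s) were used to fit the PSS reducer (e.g. %s)",
        length(leaked), leaked[1]))
    }
  }
  pr <- predict_proba(model, test_x)
  pred <- ifelse(pr[, "driver"] >= pr[, "passenger"], "driver", "passenger")
  cm <- confusion_from_labels(pred, test_labels)
  structure(list(confusion = cm,
                 metrics = metrics_from_confusion(cm),
                 scores = pr[, "driver"],
                 n_test = nrow(test_x)),
            class = "holdout_report")
}

#' @export
print.holdout_report <- function(x, ...) {
  cm <- x$confusion
  cat(sprintf("holdout_report: n = %d | TP %d  FP %d  TN %d  FN %d\n",
              x$n_test, cm$tp, cm$fp, cm$tn, cm$fn))
  print(render_metrics_percent(x$metrics))
  invisible(x)
}

#' Write evaluation reports as TSV and JSON
#'
#' `write_cv_report` emits the per-metric mean/variance table;
#' `write_holdout_report` emits the confusion counts in TP, FP, TN, FN
#' column order followed by the percentage-rendered metrics.
#'
#' @param report The report object.
#' @param path Output TSV path; a JSON twin is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  write.table(report$metrics, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(trainer = report$trainer, folds = report$folds,
         repeats = report$repeats, seed = report$seed,
         n_features = report$n_features, variance_over = report$variance_over,
         metrics = report$metrics),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cv_report
#' @export
write_holdout_report <- function(report, path) {
  cm <- report$confusion
  df <- data.frame(TP = cm$tp, FP = cm$fp, TN = cm$tn, FN = cm$fn,
                   t(render_metrics_percent(report$metrics)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(confusion = list(TP = cm$tp, FP = cm$fp, TN = cm$tn, FN = cm$fn),
         metrics = report$metrics),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
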