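#' Incremental feature selection (IFS)
#'
#' Walks the ranking from the top: for every k the top-k feature prefix is
#' evaluated by repeated stratified cross-validation and the mean accuracy
#' and its variance over repeats recorded. The optimal size `best_k` is the
#' smallest k attaining the maximum mean accuracy (parsimony on ties). Only
#' prefixes of the ranking are ever evaluated.
#'
#' @param x Numeric sample-by-feature matrix with column names.
#' @param labels Driver/passenger labels.
#' @param ranking A `feature_ranking` covering (a subset of) the columns of
#'   `x`; all its features must exist in `x`.
#' @param trainer Trainer object (default [rotation_forest_trainer()]).
#' @param folds,repeats,seed Passed to [cross_validate()] (defaults 5, 5).
#' @param max_k Evaluate prefixes up to this size (default: the full
#'   ranking).
#' @param audit Optional environment collecting every feature set handed to
#'   the trainer (see [cross_validate()]).
#' @return Object of class `ifs_curve`: data frame `curve` (k,
#'   mean_accuracy, variance), `best_k`, `best_accuracy`, run metadata.
#' @export
ifs <- function(x, labels, ranking, trainer = rotation_forest_trainer(),
                folds = 5, repeats = 5, seed = 1,
                max_k = nrow(ranking), audit = NULL) {
  x <- as.matrix(x)
  missing_feats <- setdiff(ranking$feature, colnames(x))
  if (length(missing_feats) > 0L) {
    stop_validation(sprintf("ranking names feature(s) absent from the matrix: %s",
                            paste(head(missing_feats, 3), collapse = ", ")))
  }
  max_k <- min(max_k, nrow(ranking))
  ks <- seq_len(max_k)
  mean_acc <- numeric(length(ks))
  var_acc <- numeric(length(ks))
  for (k in ks) {
    feats <- ranking$feature[seq_len(k)]
    rep_k <- cross_validate(x[, feats, drop = FALSE], labels, trainer,
                            folds = folds, repeats = repeats, seed = seed,
                            audit = audit)
    acc_row <- rep_k$metrics[rep_k$metrics$metric == "accuracy", ]
    mean_acc[k] <- acc_row$mean
    var_acc[k] <- acc_row$variance
  }
  best_k <- which.max(mean_acc)  # first max: smallest k on ties
  structure(list(curve = data.frame(k = ks, mean_accuracy = mean_acc,
                                    variance = var_acc),
                 best_k = best_k,
                 best_accuracy = mean_acc[best_k],
                 method = ranking$method[1],
                 trainer = trainer$name,
                 folds = folds, repeats = repeats, seed = seed),
            class = "ifs_curve")
}

#' @export
print.ifs_curve <- function(x, ...) {
  cat(sprintf("ifs_curve: %s ranking, %s, k = 1..%d, best_k = %d (mean accuracy %.4f)\n",
              x$method, x$trainer, nrow(x$curve), x$best_k, x$best_accuracy))
  invisible(x)
}

#' Write an IFS curve to TSV
#'
#' Columns k, mean_accuracy, variance — ready for plotting the accuracy-vs-k
#' selection curve.
#'
#' @param curve An `ifs_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ifs_curve <- function(curve, path) {
  write.table(curve$curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
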