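#' DX discriminant score of one feature
#'
#' Fisher-style ratio of between-class separation to within-class spread:
#' \deqn{DX = \frac{(\mu_{pos} - \mu_{neg})^2}{\sigma^2_{pos} + \sigma^2_{neg}}}
#' with class means and sample (n-1) variances taken over driver (positive)
#' and passenger (negative) samples. A zero denominator with separated means
#' yields `Inf` (such a feature ranks above every finite score); a zero
#' denominator with equal means yields 0.
#'
#' @param values Numeric feature column, one value per sample.
#' @param labels Driver/passenger labels, both classes with >= 2 samples.
#' @return Nonnegative scalar (possibly `Inf`).
#' @examples
#' dx_score(c(1, 3, -1, 1), c("driver", "driver", "passenger", "passenger"))
#' @export
dx_score <- function(values, labels) {
  labels <- normalize_labels(labels)
  pos <- values[labels == "driver"]
  neg <- values[labels == "passenger"]
  if (length(pos) < 2L || length(neg) < 2L) {
    stop_validation("DX undefined without two classes of >= 2 samples each")
  }
  num <- (mean(pos) - mean(neg))^2
  den <- var(pos) + var(neg)
  if (den == 0) {
    if (num == 0) return(0)
    return(Inf)
  }
  num / den
}

# Vectorized DX over the columns of a matrix (same definition as dx_score).
dx_scores_matrix <- function(x, labels) {
  labels <- normalize_labels(labels)
  pos <- x[labels == "driver", , drop = FALSE]
  neg <- x[labels == "passenger", , drop = FALSE]
  if (nrow(pos) < 2L || nrow(neg) < 2L) {
    stop_validation("DX undefined without two classes of >= 2 samples each")
  }
  num <- (colMeans(pos) - colMeans(neg))^2
  den <- apply(pos, 2, var) + apply(neg, 2, var)
  s <- ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den)
  unname(s)
}

new_feature_ranking <- function(features, scores, method) {
  structure(data.frame(rank = seq_along(features),
                       feature = features,
                       score = scores,
                       method = method,
                       stringsAsFactors = FALSE),
            class = c("feature_ranking", "data.frame"))
}

#' Rank all features by DX score
#'
#' Scores every column and sorts in non-increasing score order; ties (and
#' infinite scores among themselves) are broken by original column order.
#'
#' @param x Numeric sample-by-feature matrix with column names.
#' @param labels Driver/passenger labels.
#' @return A `feature_ranking` data frame with columns `rank`, `feature`,
#'   `score`, `method`.
#' @export
rank_dx <- function(x, labels) {
  scores <- dx_scores_matrix(x, labels)
  if (all(scores == 0)) warning("all DX scores are zero (constant feature matrix?)")
  ord <- order(-scores, seq_along(scores))
  new_feature_ranking(colnames(x)[ord], scores[ord], "dx")
}

#' Discretize a numeric column for mutual-information estimation
#'
#' Default scheme: three bins split at mean - sd and mean + sd (values at or
#' below the lower threshold -> 1, at or above the upper -> 3, else 2).
#' Columns already valued in \{0, 1\} pass through unchanged (shifted to
#' bins 1/2); a zero-variance column collapses to a single bin with a
#' warning.
#'
#' @param values Numeric column.
#' @return Integer bin codes.
#' @export
discretize <- function(values) {
  u <- unique(values[!is.na(values)])
  if (all(u %in% c(0, 1))) return(as.integer(values) + 1L)
  m <- mean(values)
  s <- sd(values)
  if (!is.finite(s) || s == 0) {
    warning("zero-variance column discretized to a single bin")
    return(rep(1L, length(values)))
  }
  ifelse(values <= m - s, 1L, ifelse(values >= m + s, 3L, 2L))
}

#' @rdname discretize
#' @param x Numeric matrix; each column is discretized independently.
#' @export
discretize_matrix <- function(x) {
  apply(x, 2, discretize)
}

#' Plug-in mutual information of two discrete columns
#'
#' Empirical mutual information over the joint contingency table,
#' \eqn{I(x, y) = \sum p(x,y) \log\frac{p(x,y)}{p(x)p(y)}}, in nats
#' (natural log). Nonnegative; zero iff the empirical joint factorizes.
#'
#' @param x,y Discrete (integer/factor) columns of equal length.
#' @return Scalar mutual information in nats.
#' @examples
#' mutual_information(rep(1:3, 4), rep(1:3, 4))  # log(3)
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop_validation("column lengths differ")
  joint <- table(x, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  expected <- outer(px, py)
  max(0, sum(joint[nz] * log(joint[nz] / expected[nz])))
}

#' Rank features by minimum-redundancy maximum-relevance (mRMR)
#'
#' Greedy incremental ranking over mutual information. Continuous columns
#' are first discretized (three bins at mean +/- sd). The first feature
#' maximizes relevance I(x; class); each subsequent feature maximizes
#' relevance minus the mean redundancy to already-selected features (MID,
#' the additive default) or relevance divided by mean redundancy (MIQ). The
#' loop runs the full N rounds, producing a complete ranking; ties break by
#' original column order.
#'
#' @param x Numeric sample-by-feature matrix with column names.
#' @param labels Driver/passenger labels.
#' @param variant `"MID"` (difference, default) or `"MIQ"` (quotient).
#' @return A `feature_ranking` with the selection-step score of each feature.
#' @export
rank_mrmr <- function(x, labels, variant = c("MID", "MIQ")) {
  variant <- match.arg(variant)
  labels <- normalize_labels(labels)
  if (nlevels(droplevels(labels)) < 2L) stop_validation("mRMR requires both classes")
  n <- ncol(x)
  d <- discretize_matrix(x)
  cls <- as.integer(labels)
  relevance <- vapply(seq_len(n), function(j) mutual_information(d[, j], cls), numeric(1))
  selected <- integer(0)
  sel_scores <- numeric(0)
  # redundancy[j] accumulates sum of MI(j, s) over selected s
  red_sum <- numeric(n)
  remaining <- seq_len(n)
  for (round in seq_len(n)) {
    if (length(selected) == 0L) {
      score <- relevance[remaining]
    } else {
      mean_red <- red_sum[remaining] / length(selected)
      score <- if (variant == "MID") {
        relevance[remaining] - mean_red
      } else {
        relevance[remaining] / pmax(mean_red, .Machine$double.eps)
      }
    }
    pick <- remaining[which.max(score)]  # which.max takes the first max: index tie-break
    sel_scores <- c(sel_scores, max(score))
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) > 0L) {
      red_sum[remaining] <- red_sum[remaining] +
        vapply(remaining, function(j) mutual_information(d[, j], d[, pick]), numeric(1))
    }
  }
  new_feature_ranking(colnames(x)[selected], sel_scores, "mrmr")
}

#' Write a feature ranking to TSV
#'
#' @param ranking A `feature_ranking`.
#' @param path Output path (columns rank, feature, score, method).
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  write.table(ranking, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  for (col in c("rank", "feature", "score")) {
    if (!col %in% names(df)) stop_format(sprintf("ranking file lacks column '%s'", col))
  }
  structure(df, class = c("feature_ranking", "data.frame"))
}
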