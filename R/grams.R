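#' Names of the 436 dipeptide gram components
#'
#' Component ordering is fixed: the first 400 components are ordered residue
#' pairs of the 20-letter alphabet, component `(i-1)*20 + j` counting the
#' pair (residue i, residue j) in alphabetical one-letter order; the last 36
#' are ordered group pairs of the reduced 6-letter alphabet, component
#' `400 + (g1-1)*6 + g2` counting group pair (g1, g2).
#'
#' @return Character vector of length 436 (`g2.XY` then `g6.a.b`).
#' @export
gram_feature_names <- function() {
  n400 <- as.vector(t(outer(AA20, AA20, function(a, b) paste0("g2.", a, b))))
  n36 <- as.vector(t(outer(1:6, 1:6, function(a, b) paste0("g6.", a, ".", b))))
  c(n400, n36)
}

#' Dipeptide gram counts of a protein sequence
#'
#' Counts every ordered pair of consecutive residues (2-gram) over the full
#' sequence: 400 components for the 20-letter alphabet, then 36 components
#' after recoding the sequence through the reduced [six_letter_alphabet()].
#' Counts are raw occurrences (each block sums to L - 1 for a sequence of
#' length L); set `normalize = TRUE` for per-block relative frequencies.
#'
#' @param sequence Protein sequence over the 20 standard residues, length >= 2.
#' @param normalize Divide each block by L - 1 (default `FALSE`).
#' @return Named numeric vector of length 436 (see [gram_feature_names()]).
#' @examples
#' gram_counts("AAG")[c("g2.AA", "g2.AG", "g6.4.4")]
#' @export
gram_counts <- function(sequence, normalize = FALSE) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(chars) < 2L) stop_validation("gram extraction needs sequence length >= 2")
  bad <- unique(chars[!chars %in% AA20])
  if (length(bad) > 0L) {
    stop_validation(sprintf("nonstandard residue(s) in sequence: %s",
                            paste(bad, collapse = ", ")))
  }
  i1 <- match(chars[-length(chars)], AA20)
  i2 <- match(chars[-1], AA20)
  v400 <- tabulate((i1 - 1L) * 20L + i2, nbins = 400L)
  groups <- six_letter_alphabet()[chars]
  g1 <- groups[-length(groups)]
  g2 <- groups[-1]
  v36 <- tabulate((g1 - 1L) * 6L + g2, nbins = 36L)
  v <- c(v400, v36)
  if (normalize) v <- v / (length(chars) - 1L)
  setNames(v, gram_feature_names())
}

# Gram matrix for a set of proteins: one row per protein, 436 columns.
gram_matrix <- function(proteins, normalize = FALSE) {
  t(vapply(proteins, gram_counts, numeric(436L), normalize = normalize))
}

#' Linear correlation coefficient against a mean gram profile
#'
#' Pearson-form correlation between a sample's gram vector and a reference
#' mean profile, computed across the 436 components:
#' \deqn{LCC = \frac{n\sum x_i \bar{x}_i - \sum x_i \sum \bar{x}_i}
#'   {\sqrt{n\sum x_i^2 - (\sum x_i)^2}\sqrt{n\sum \bar{x}_i^2 - (\sum \bar{x}_i)^2}}}
#' It summarizes how typical a sequence's dipeptide composition is of the
#' training set. Zero variance in either vector leaves the coefficient
#' undefined; it is reported as `NA` with a warning.
#'
#' @param x Sample gram vector.
#' @param mean_profile Reference profile of the same length (the per-component
#'   mean over a training set).
#' @return Scalar in \[-1, 1\], or `NA` for a zero-variance input.
#' @export
lcc <- function(x, mean_profile) {
  if (length(x) != length(mean_profile)) {
    stop_validation("gram vector and mean profile lengths differ")
  }
  n <- length(x)
  sx <- sum(x); sm <- sum(mean_profile)
  vx <- n * sum(x^2) - sx^2
  vm <- n * sum(mean_profile^2) - sm^2
  if (vx <= 0 || vm <= 0) {
    warning("LCC undefined for zero-variance vector; returning NA")
    return(NA_real_)
  }
  (n * sum(x * mean_profile) - sx * sm) / sqrt(vx * vm)
}
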