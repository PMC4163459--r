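#' Fit the protein-sequence-specific (PSS) gram reducer
#'
#' Scores every gram column of a training gram matrix with the DX
#' discriminant (see [dx_score()]), records the `top_k` highest-scoring
#' column indices (ties broken by lower column index), and stores the
#' per-column mean profile used by the [lcc()] summary. The reducer must be
#' fitted on training samples only; the ids of the rows it saw are retained
#' so downstream evaluation can verify no test sample leaked in.
#'
#' @param grams Training gram matrix (samples x 436), rownames = sample ids.
#' @param labels Driver/passenger labels, both classes present.
#' @param top_k Number of gram columns to keep (default 30).
#' @param domain Rank over `"all"` 436 gram columns (default) or the first
#'   `"aa400"` 20-letter columns only.
#' @param mean_profile Average the LCC reference over `"all"` training
#'   samples (default) or over the `"driver"` class only.
#' @param on_constant With an all-constant gram matrix, `"zero"` keeps the
#'   all-zero scores and selects by index order with a warning;
#'   `"error"` aborts.
#' @return Object of class `pss_reducer` with elements `selected` (column
#'   indices), `selected_names`, `mean_profile`, `profile_over`,
#'   `fitted_ids`, `top_k`.
#' @export
fit_pss_reducer <- function(grams, labels, top_k = 30,
                            domain = c("all", "aa400"),
                            mean_profile = c("all", "driver"),
                            on_constant = c("zero", "error")) {
  domain <- match.arg(domain)
  mean_profile <- match.arg(mean_profile)
  on_constant <- match.arg(on_constant)
  labels <- normalize_labels(labels)
  if (ncol(grams) != 436L) stop_validation("gram matrix must have 436 columns")
  if (nrow(grams) < 4L || nlevels(droplevels(labels)) < 2L) {
    stop_validation("DX undefined without two classes")
  }
  candidates <- if (domain == "all") seq_len(436L) else seq_len(400L)
  if (top_k < 1L || top_k > length(candidates)) {
    stop_config(sprintf("top_k must be in [1, %d]", length(candidates)))
  }
  scores <- dx_scores_matrix(grams[, candidates, drop = FALSE], labels)
  if (all(scores == 0)) {
    if (on_constant == "error") stop_validation("all gram DX scores are zero")
    warning("all gram DX scores are zero; selecting by column index")
  }
  ord <- candidates[order(-scores, seq_along(scores))]
  selected <- ord[seq_len(top_k)]
  profile_rows <- if (mean_profile == "all") seq_len(nrow(grams)) else which(labels == "driver")
  structure(list(
    selected = selected,
    selected_names = gram_feature_names()[selected],
    scores = setNames(scores, gram_feature_names()[candidates]),
    mean_profile = colMeans(grams[profile_rows, , drop = FALSE]),
    profile_over = mean_profile,
    fitted_ids = rownames(grams),
    top_k = top_k,
    domain = domain
  ), class = "pss_reducer")
}

#' @export
print.pss_reducer <- function(x, ...) {
  cat(sprintf("pss_reducer: top %d of %s gram columns (DX-ranked), profile over %s, fitted on %d samples\n",
              x$top_k, if (x$domain == "all") "436" else "400",
              x$profile_over, length(x$fitted_ids)))
  invisible(x)
}

#' Encode PSS features for every mutation of a dataset
#'
#' PSS features are sequence-level: each mutation inherits the `top_k`
#' selected gram counts of its source protein plus the LCC of the protein's
#' full 436-gram vector against the reducer's training mean profile
#' (`top_k + 1 = 31` features by default). Two mutations on the same protein
#' therefore share identical PSS vectors. By default grams are taken from
#' the wild-type sequence; `sequence = "mutant"` substitutes the mutant
#' residue at the mutation position first.
#'
#' @param ds A `mutation_dataset`.
#' @param reducer A fitted [fit_pss_reducer()] object.
#' @param sequence `"wild"` (default) or `"mutant"`.
#' @return Numeric matrix (n mutations x top_k + 1); last column `pss.lcc`.
#' @export
encode_pss <- function(ds, reducer, sequence = c("wild", "mutant")) {
  sequence <- match.arg(sequence)
  if (!inherits(reducer, "pss_reducer")) {
    stop_validation("reducer must be a fitted pss_reducer")
  }
  m <- ds$mutations
  if (sequence == "wild") {
    # one gram vector per distinct protein, shared across its mutations
    gm <- gram_matrix(ds$proteins[unique(m$protein_id)])
    rows <- gm[m$protein_id, , drop = FALSE]
  } else {
    seqs <- ds$proteins[m$protein_id]
    substr(seqs, m$position, m$position) <- m$mutant
    rows <- gram_matrix(unname(seqs))
  }
  lcc_vals <- apply(rows, 1, lcc, mean_profile = reducer$mean_profile)
  out <- cbind(rows[, reducer$selected, drop = FALSE], lcc_vals)
  colnames(out) <- c(paste0("pss.", reducer$selected_names), "pss.lcc")
  rownames(out) <- mutation_ids(ds)
  out
}
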