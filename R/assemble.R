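#' Feature-extraction configuration
#'
#' Bundles the encoder tables and the toggles that define the feature space.
#' With all defaults the assembled width is 15 (AARC) + 51 (SSM) +
#' `pss_top_k` + 1 (PSS) + 29 (AF) = 126.
#'
#' @param scales List of [property_scale()] objects (default 15).
#' @param matrices List of [substitution_matrix()] objects (default 51).
#' @param af_schema_df Annotated-feature schema (default 29 features); `NULL`
#'   drops the AF family.
#' @param pss_top_k Gram columns kept by the PSS reducer (default 30).
#' @param pss_sequence Sequence the grams are computed from: `"wild"`
#'   (default) or `"mutant"`.
#' @param gram_domain Rank grams over `"all"` 436 columns (default) or
#'   `"aa400"` only.
#' @param lcc_profile LCC mean profile over `"all"` training samples
#'   (default) or `"driver"` only.
#' @param normalize_grams Use per-block gram frequencies instead of raw
#'   counts (default `FALSE`).
#' @return Object of class `feature_config`.
#' @export
feature_config <- function(scales = default_property_scales(),
                           matrices = default_substitution_matrices(),
                           af_schema_df = default_af_schema(),
                           pss_top_k = 30,
                           pss_sequence = c("wild", "mutant"),
                           gram_domain = c("all", "aa400"),
                           lcc_profile = c("all", "driver"),
                           normalize_grams = FALSE) {
  structure(list(scales = scales,
                 matrices = matrices,
                 af_schema = af_schema_df,
                 pss_top_k = pss_top_k,
                 pss_sequence = match.arg(pss_sequence),
                 gram_domain = match.arg(gram_domain),
                 lcc_profile = match.arg(lcc_profile),
                 normalize_grams = normalize_grams),
            class = "feature_config")
}

expected_width <- function(config) {
  length(config$scales) + length(config$matrices) + config$pss_top_k + 1L +
    if (is.null(config$af_schema)) 0L else nrow(config$af_schema)
}

#' Fit the trainable parts of the feature extractor on training data
#'
#' Two encoder families have trainable state that must never see test
#' samples: the PSS reducer (DX gram ranking and LCC mean profile) and the
#' numeric AF imputation medians. This fits both on the given labeled
#' training dataset and freezes them into an extractor object.
#'
#' @param train_ds Labeled training `mutation_dataset`.
#' @param config A [feature_config()].
#' @return Object of class `feature_extractor` holding the config, the
#'   fitted `pss_reducer`, the AF medians, and the training sample ids.
#' @export
fit_feature_extractor <- function(train_ds, config = feature_config()) {
  labels <- mutation_labels(train_ds)
  if (anyNA(labels)) stop_validation("training dataset must be fully labeled")
  m <- train_ds$mutations
  if (config$pss_sequence == "wild") {
    per_protein <- gram_matrix(train_ds$proteins[unique(m$protein_id)],
                               normalize = config$normalize_grams)
    grams <- per_protein[m$protein_id, , drop = FALSE]
  } else {
    seqs <- train_ds$proteins[m$protein_id]
    substr(seqs, m$position, m$position) <- m$mutant
    grams <- gram_matrix(unname(seqs), normalize = config$normalize_grams)
  }
  rownames(grams) <- mutation_ids(train_ds)
  reducer <- fit_pss_reducer(grams, labels, top_k = config$pss_top_k,
                             domain = config$gram_domain,
                             mean_profile = config$lcc_profile)
  medians <- NULL
  if (!is.null(config$af_schema)) {
    num <- config$af_schema$name[config$af_schema$kind == "numeric"]
    medians <- vapply(num, function(nm) {
      v <- if (nm %in% names(m)) suppressWarnings(as.numeric(m[[nm]])) else NA_real_
      med <- stats::median(v, na.rm = TRUE)
      if (is.finite(med)) med else 0
    }, numeric(1))
  }
  structure(list(config = config,
                 reducer = reducer,
                 af_medians = medians,
                 fitted_ids = mutation_ids(train_ds)),
            class = "feature_extractor")
}

#' Assemble the full feature matrix for a dataset
#'
#' Concatenates the four encoder families per sample, AARC then SSM then PSS
#' then AF, with a provenance tag per feature. Deterministic: the same
#' dataset, extractor and config always produce an identical matrix.
#'
#' @param ds A `mutation_dataset` (training or test).
#' @param extractor A fitted [fit_feature_extractor()].
#' @return Numeric matrix (samples x features) with attribute `provenance`
#'   (named character vector over `AARC`, `SSM`, `PSS`, `AF`), rownames =
#'   mutation ids.
#' @export
assemble_features <- function(ds, extractor) {
  if (!inherits(extractor, "feature_extractor")) {
    stop_validation("extractor must come from fit_feature_extractor()")
  }
  config <- extractor$config
  aarc <- encode_aarc(ds, config$scales)
  ssm <- encode_ssm(ds, config$matrices)
  pss <- encode_pss(ds, extractor$reducer, sequence = config$pss_sequence)
  blocks <- list(aarc, ssm, pss)
  prov <- c(rep("AARC", ncol(aarc)), rep("SSM", ncol(ssm)), rep("PSS", ncol(pss)))
  if (!is.null(config$af_schema)) {
    af <- encode_af(ds, config$af_schema, medians = extractor$af_medians)
    blocks <- c(blocks, list(af))
    prov <- c(prov, rep("AF", ncol(af)))
  }
  out <- do.call(cbind, blocks)
  if (ncol(out) != expected_width(config)) {
    stop(sprintf("internal consistency error: assembled %d features, config expects %d",
                 ncol(out), expected_width(config)))
  }
  if (anyDuplicated(colnames(out))) {
    stop("internal consistency error: duplicate feature names")
  }
  attr(out, "provenance") <- setNames(prov, colnames(out))
  out
}

#' Feature provenance tags
#'
#' @param fm A matrix from [assemble_features()].
#' @return Named character vector mapping feature name to family
#'   (`AARC`/`SSM`/`PSS`/`AF`).
#' @export
provenance <- function(fm) {
  attr(fm, "provenance")
}

#' Write a feature matrix (plus labels) to TSV with a provenance sidecar
#'
#' @param fm Feature matrix with rownames.
#' @param labels Optional labels written as a `label` column.
#' @param path Output TSV; the provenance map goes to `<path>.provenance.json`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path, labels = NULL) {
  df <- data.frame(sample_id = rownames(fm), check.names = FALSE)
  if (!is.null(labels)) df$label <- as.character(labels)
  df <- cbind(df, as.data.frame(fm, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- provenance(fm)
  if (!is.null(prov)) {
    jsonlite::write_json(as.list(prov), paste0(path, ".provenance.json"),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop_format("feature TSV lacks 'sample_id' column")
  labels <- NULL
  if ("label" %in% names(df)) labels <- df$label
  feat_cols <- setdiff(names(df), c("sample_id", "label"))
  fm <- as.matrix(df[, feat_cols, drop = FALSE])
  rownames(fm) <- df$sample_id
  sidecar <- paste0(path, ".provenance.json")
  if (file.exists(sidecar)) {
    prov <- unlist(jsonlite::read_json(sidecar))
    attr(fm, "provenance") <- prov[colnames(fm)]
  }
  list(features = fm, labels = labels)
}
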