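#' Encode amino-acid residue-change (AARC) features
#'
#' One feature per property scale: the wild-type property value minus the
#' mutant property value, `scale(W) - scale(M)`. Antisymmetric in the
#' substitution direction.
#'
#' @param ds A `mutation_dataset`.
#' @param scales List of [property_scale()] objects (default the 15 bundled
#'   scales).
#' @return Numeric matrix, n mutations x length(scales), columns `aarc.<name>`.
#' @export
encode_aarc <- function(ds, scales = default_property_scales()) {
  m <- ds$mutations
  out <- vapply(scales, function(sc) {
    v <- unclass(sc)
    miss <- setdiff(unique(c(m$wild, m$mutant)), names(v))
    if (length(miss) > 0L) {
      stop_config(sprintf("property scale '%s' lacks residue(s): %s",
                          attr(sc, "name"), paste(miss, collapse = ", ")))
    }
    v[m$wild] - v[m$mutant]
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(mutation_ids(ds),
                                paste0("aarc.", vapply(scales, attr, character(1), "name"))))
  out
}

#' Encode substitution-scoring-matrix (SSM) features
#'
#' One feature per matrix: the element indexed by (wild residue, mutant
#' residue).
#'
#' @param ds A `mutation_dataset`.
#' @param matrices List of [substitution_matrix()] objects (default the 51
#'   bundled matrices).
#' @return Numeric matrix, n mutations x length(matrices), columns `ssm.<name>`.
#' @export
encode_ssm <- function(ds, matrices = default_substitution_matrices()) {
  m <- ds$mutations
  idx <- cbind(match(m$wild, AA20), match(m$mutant, AA20))
  if (anyNA(idx)) stop_validation("nonstandard residue in mutation table")
  out <- vapply(matrices, function(mat) unclass(mat)[idx], numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(mutation_ids(ds),
                                paste0("ssm.", vapply(matrices, attr, character(1), "name"))))
  out
}

#' Default annotated-feature schema
#'
#' The bundled AF schema of 29 features: 14 binary attributes (presence
#' flags of the kind curated in protein annotation databases — domain,
#' active site, binding site, modification flags and so on, which may be
#' unavailable for a given mutation) and 15 numeric attributes. Swappable
#' via [af_schema()].
#'
#' @return Data frame with columns `name`, `kind` (`binary` or `numeric`).
#' @export
default_af_schema <- function() {
  af_schema(
    names = c(sprintf("af.bin%02d", 1:14), sprintf("af.num%02d", 1:15)),
    kinds = c(rep("binary", 14), rep("numeric", 15)))
}

#' @rdname default_af_schema
#' @param names Feature names.
#' @param kinds `"binary"` or `"numeric"`, one per feature.
#' @export
af_schema <- function(names, kinds) {
  kinds <- match.arg(kinds, c("binary", "numeric"), several.ok = TRUE)
  if (length(names) != length(kinds)) stop_config("af_schema names/kinds lengths differ")
  if (anyDuplicated(names)) stop_config("af_schema names must be unique")
  data.frame(name = names, kind = kinds, stringsAsFactors = FALSE)
}

#' Encode annotated features (AF)
#'
#' Pulls the schema's columns from the dataset's annotated values in schema
#' order. Missing binary values are imputed to 0 (absence-coded); missing
#' numeric values are imputed to the training-set median supplied in
#' `medians` (or the current data's median when none is given). Imputation
#' counts are reported in a message.
#'
#' @param ds A `mutation_dataset`.
#' @param schema An [af_schema()] (default 29 features).
#' @param medians Optional named numeric vector of training medians for
#'   numeric features (from [fit_feature_extractor()]).
#' @return Numeric matrix, n mutations x nrow(schema).
#' @export
encode_af <- function(ds, schema = default_af_schema(), medians = NULL) {
  m <- ds$mutations
  n <- nrow(m)
  out <- matrix(NA_real_, n, nrow(schema),
                dimnames = list(mutation_ids(ds), schema$name))
  imputed <- setNames(integer(nrow(schema)), schema$name)
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    vals <- if (nm %in% names(m)) suppressWarnings(as.numeric(m[[nm]])) else rep(NA_real_, n)
    if (schema$kind[i] == "binary") {
      bad <- !is.na(vals) & !vals %in% c(0, 1)
      if (any(bad)) {
        stop_validation(sprintf("binary annotated feature '%s' has non-0/1 value '%s' at row %d",
                                nm, vals[which(bad)[1]], which(bad)[1]))
      }
      imputed[nm] <- sum(is.na(vals))
      vals[is.na(vals)] <- 0
    } else {
      fill <- if (!is.null(medians) && nm %in% names(medians)) {
        medians[[nm]]
      } else {
        stats::median(vals, na.rm = TRUE)
      }
      if (!is.finite(fill)) fill <- 0
      imputed[nm] <- sum(is.na(vals))
      vals[is.na(vals)] <- fill
    }
    out[, i] <- vals
  }
  if (sum(imputed) > 0L) {
    message(sprintf("encode_af: imputed %d missing value(s) across %d feature(s)",
                    sum(imputed), sum(imputed > 0L)))
  }
  attr(out, "imputed") <- imputed
  out
}
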