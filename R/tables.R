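# Property scales (one number per residue) and substitution matrices
# (one number per ordered residue pair), with TSV IO in an AAindex-like
# layout and a documented default set: 15 classic physicochemical scales and
# 51 substitution matrices (10 BLOSUM/PAM log-odds tables plus 41
# property-distance matrices derived from further AAindex scales).

#' Construct an amino-acid property scale
#'
#' @param name Scale identifier (e.g. an AAindex accession).
#' @param values Named numeric vector covering exactly the 20 standard
#'   residues; all values finite.
#' @return Object of class `property_scale` (named numeric, attribute `name`).
#' @export
property_scale <- function(name, values) {
  if (!setequal(names(values), AA20)) {
    missing <- setdiff(AA20, names(values))
    stop_config(sprintf("property scale '%s' must cover the 20 standard residues%s",
                        name,
                        if (length(missing)) paste0(" (missing: ", paste(missing, collapse = ","), ")") else ""))
  }
  v <- as.numeric(values[AA20])
  if (any(!is.finite(v))) stop_config(sprintf("property scale '%s' has non-finite values", name))
  structure(setNames(v, AA20), name = name, class = "property_scale")
}

#' Construct a substitution matrix
#'
#' @param name Matrix identifier.
#' @param values 20 x 20 numeric matrix with residue dimnames; entry
#'   `[i, j]` scores the wild residue i to mutant residue j substitution.
#'   Symmetry is not assumed.
#' @return Object of class `substitution_matrix`.
#' @export
substitution_matrix <- function(name, values) {
  if (!is.matrix(values) || !setequal(rownames(values), AA20) ||
      !setequal(colnames(values), AA20)) {
    stop_config(sprintf("substitution matrix '%s' must be 20 x 20 with residue dimnames", name))
  }
  m <- values[AA20, AA20]
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop_config(sprintf("substitution matrix '%s' has non-finite entries", name))
  structure(m, name = name, class = c("substitution_matrix", "matrix", "array"))
}

#' @rdname property_scale
#' @param path TSV with header `residue<TAB>value`, 20 data rows.
#' @export
read_property_scale <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("residue", "value") %in% names(df))) {
    stop_format(sprintf("property scale file '%s' needs columns residue, value", path))
  }
  property_scale(name, setNames(df$value, df$residue))
}

#' @rdname property_scale
#' @param scale A `property_scale` to serialize.
#' @export
write_property_scale <- function(scale, path) {
  write.table(data.frame(residue = names(scale), value = as.numeric(scale)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname substitution_matrix
#' @param path TSV: header row of the 20 residue letters, then 20 rows each
#'   starting with the wild-type residue letter.
#' @export
read_substitution_matrix <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, row.names = 1)
  substitution_matrix(name, as.matrix(df))
}

#' @rdname substitution_matrix
#' @param matrix_obj A `substitution_matrix` to serialize.
#' @export
write_substitution_matrix <- function(matrix_obj, path) {
  df <- as.data.frame(unclass(matrix_obj))
  write.table(cbind(residue = rownames(df), df), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

# AAindex accessions of the 15 default AARC scales: classic, orthogonal
# physicochemical descriptors (hydropathy, polarity, volume, charge,
# surface area, secondary-structure propensities, flexibility, mutability).
DEFAULT_SCALE_ACCESSIONS <- c(
  "KYTJ820101",  # hydropathy (Kyte-Doolittle)
  "GRAR740102",  # polarity (Grantham)
  "GRAR740103",  # volume (Grantham)
  "ZIMJ680104",  # isoelectric point
  "CHOC760101",  # accessible surface area in tripeptide
  "BIGC670101",  # residue volume
  "FAUJ880103",  # normalized van der Waals volume
  "JANJ780101",  # average accessible surface area
  "CHOP780201",  # alpha-helix propensity
  "CHOP780202",  # beta-sheet propensity
  "CHOP780203",  # beta-turn propensity
  "KLEP840101",  # net charge
  "FASG760101",  # molecular weight
  "DAYM780201",  # relative mutability
  "BHAR880101"   # average flexibility
)

# Names of the Biostrings log-odds matrices used in the default SSM set.
DEFAULT_LOGODDS_MATRICES <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80",
                              "BLOSUM100", "PAM30", "PAM40", "PAM70",
                              "PAM120", "PAM250")

.table_cache <- new.env(parent = emptyenv())

# Load the seqinr AAindex collection once.
aaindex_collection <- function() {
  if (is.null(.table_cache$aaindex)) {
    e <- new.env()
    utils::data("aaindex", package = "seqinr", envir = e)
    .table_cache$aaindex <- e$aaindex
  }
  .table_cache$aaindex
}

aaindex_scale <- function(accession) {
  idx <- aaindex_collection()
  entry <- idx[[accession]]
  if (is.null(entry)) stop_config(sprintf("AAindex accession '%s' not found", accession))
  one <- toupper(vapply(names(entry$I), function(n) seqinr::a(n), character(1)))
  property_scale(accession, setNames(as.numeric(entry$I), one))
}

#' Default amino-acid property scales
#'
#' The 15 bundled AARC scales: classic physicochemical descriptors drawn
#' from the AAindex collection (hydropathy, polarity, volume, isoelectric
#' point, accessible surface area, van der Waals volume, secondary-structure
#' propensities, net charge, molecular weight, mutability, flexibility).
#' Fully swappable: any list of [property_scale()] objects works wherever
#' this default is accepted.
#'
#' @return Named list of 15 `property_scale` objects.
#' @export
default_property_scales <- function() {
  if (is.null(.table_cache$scales)) {
    .table_cache$scales <- setNames(
      lapply(DEFAULT_SCALE_ACCESSIONS, aaindex_scale),
      DEFAULT_SCALE_ACCESSIONS)
  }
  .table_cache$scales
}

biostrings_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  substitution_matrix(name, e[[name]][AA20, AA20])
}

# A substitution matrix derived from one property scale: score of i -> j is
# minus the absolute property difference, so conservative substitutions
# score near 0 and radical ones strongly negative.
property_distance_matrix <- function(scale) {
  v <- as.numeric(scale)
  m <- -abs(outer(v, v, "-"))
  dimnames(m) <- list(AA20, AA20)
  substitution_matrix(paste0("DIST.", attr(scale, "name")), m)
}

#' Default substitution matrices
#'
#' The 51 bundled SSM tables: the ten standard BLOSUM/PAM log-odds matrices
#' (BLOSUM45/50/62/80/100, PAM30/40/70/120/250) plus 41 property-distance
#' matrices, each derived from one additional AAindex scale (the first 41
#' complete scales in collection order not already used as AARC defaults) as
#' minus the absolute between-residue property difference. Counts, not
#' identities, are what the pipeline's structure depends on; any list of
#' [substitution_matrix()] objects can be substituted.
#'
#' @return Named list of 51 `substitution_matrix` objects.
#' @export
default_substitution_matrices <- function() {
  if (is.null(.table_cache$matrices)) {
    logodds <- lapply(DEFAULT_LOGODDS_MATRICES, biostrings_matrix)
    idx <- aaindex_collection()
    complete <- names(idx)[vapply(idx, function(e) all(is.finite(e$I)), logical(1))]
    extra <- setdiff(complete, DEFAULT_SCALE_ACCESSIONS)[seq_len(41)]
    derived <- lapply(extra, function(acc) property_distance_matrix(aaindex_scale(acc)))
    mats <- c(logodds, derived)
    .table_cache$matrices <- setNames(mats, vapply(mats, attr, character(1), "name"))
  }
  .table_cache$matrices
}
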