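#' Read protein sequences from FASTA
#'
#' Reads a FASTA file into a named character vector of sequences. The record
#' id is the first whitespace-delimited token of the header line; entry order
#' is preserved and wrapped sequence lines are joined.
#'
#' @param path Path to a FASTA file.
#' @param nonstandard Policy for sequences containing letters outside the 20
#'   standard residues (B, Z, X, U, O, ...): `"error"` (default) rejects the
#'   file, `"drop"` removes the offending sequences with a warning.
#' @return Named character vector: names are protein ids, values sequences.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 description", "ACDE", ">p2", "WYW"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, nonstandard = c("error", "drop")) {
  nonstandard <- match.arg(nonstandard)
  if (!file.exists(path)) stop_format(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop_format(sprintf(
                    "cannot parse FASTA '%s': %s", path, conditionMessage(e))))
  if (length(set) == 0L) stop_format(sprintf("FASTA file '%s' contains no records", path))
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop_format(sprintf("duplicate FASTA id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  bad <- vapply(seqs, function(s) length(nonstandard_letters(s)) > 0L, logical(1))
  if (any(bad)) {
    if (nonstandard == "error") {
      stop_validation(sprintf(
        "sequence(s) with nonstandard residues: %s (use nonstandard = \"drop\" to skip them)",
        paste(ids[bad], collapse = ", ")))
    }
    warning(sprintf("dropping %d sequence(s) with nonstandard residues: %s",
                    sum(bad), paste(ids[bad], collapse = ", ")))
    seqs <- seqs[!bad]
  }
  short <- nchar(seqs) < 2L
  if (any(short)) {
    stop_validation(sprintf("sequence(s) shorter than 2 residues: %s",
                            paste(names(seqs)[short], collapse = ", ")))
  }
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param proteins Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Required columns of a mutation table.
MUTATION_COLUMNS <- c("protein_id", "position", "wild", "mutant")

#' Read a missense mutation table
#'
#' Parses a TSV with header columns `protein_id`, `position` (1-based),
#' `wild`, `mutant`, an optional `label` column (`driver`/`passenger`), and
#' any number of additional annotated-feature columns. Empty cells in
#' annotated columns become `NA`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A data frame of mutations, one row per record, in file order, with
#'   attribute `annotated_features` naming the extra columns.
#' @export
read_mutations <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("mutation table not found: %s", path))
  raw <- tryCatch(
    read.delim(path, sep = "\t", stringsAsFactors = FALSE,
               na.strings = c("NA", ""), check.names = FALSE),
    error = function(e) stop_format(sprintf("cannot parse '%s': %s",
                                            path, conditionMessage(e))))
  missing_cols <- setdiff(MUTATION_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop_format(sprintf("mutation table '%s' lacks required column(s): %s",
                        path, paste(missing_cols, collapse = ", ")))
  }
  pos <- suppressWarnings(as.integer(raw$position))
  bad_pos <- which(is.na(pos) | pos < 1L)
  if (length(bad_pos) > 0L) {
    stop_format(sprintf("non-integer or non-positive position at data row %d (file line %d)",
                        bad_pos[1], bad_pos[1] + 1L))
  }
  raw$position <- pos
  raw$wild <- toupper(as.character(raw$wild))
  raw$mutant <- toupper(as.character(raw$mutant))
  same <- which(raw$wild == raw$mutant)
  if (length(same) > 0L) {
    stop_validation(sprintf("not missense: wild == mutant ('%s') at data row %d",
                            raw$wild[same[1]], same[1]))
  }
  if ("label" %in% names(raw)) {
    ok <- is.na(raw$label) | raw$label %in% c("driver", "passenger")
    if (!all(ok)) {
      stop_format(sprintf("invalid label '%s' at data row %d (expected driver/passenger)",
                          raw$label[which(!ok)[1]], which(!ok)[1]))
    }
  }
  annotated <- setdiff(names(raw), c(MUTATION_COLUMNS, "label"))
  attr(raw, "annotated_features") <- annotated
  raw
}

#' Write a missense mutation table
#'
#' Inverse of [read_mutations()]: writes a TSV whose round-trip reproduces the
#' input, missing annotated values included (as empty cells).
#'
#' @param mutations Data frame as returned by [read_mutations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(mutations, path) {
  write.table(mutations, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Assemble and validate a mutation dataset
#'
#' Binds proteins and mutations together and enforces the domain invariants:
#' each mutation resolves to a known protein, its position is inside the
#' sequence, the stated wild-type residue matches the sequence at that
#' position, wild and mutant are standard residues, and no
#' (protein, position, wild, mutant) tuple occurs twice. Rows whose wild-type
#' residue disagrees with the sequence are rejected outright.
#'
#' @param proteins Named character vector of sequences (see [read_fasta()]).
#' @param mutations Data frame as returned by [read_mutations()].
#' @return An object of class `mutation_dataset`: a list with elements
#'   `proteins`, `mutations` and `annotated` (annotated-feature column names).
#' @examples
#' prot <- c(p1 = "MKTAYIAKQR")
#' mut <- data.frame(protein_id = "p1", position = 3, wild = "T",
#'                   mutant = "A", label = "driver")
#' mutation_dataset(prot, mut)
#' @export
mutation_dataset <- function(proteins, mutations) {
  if (is.null(names(proteins)) || any(!nzchar(names(proteins)))) {
    stop_validation("proteins must be a named character vector")
  }
  for (col in MUTATION_COLUMNS) {
    if (!col %in% names(mutations)) {
      stop_validation(sprintf("mutations lack required column '%s'", col))
    }
  }
  unknown <- setdiff(unique(mutations$protein_id), names(proteins))
  if (length(unknown) > 0L) {
    stop_validation(sprintf("mutation(s) reference unknown protein(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  for (i in seq_len(nrow(mutations))) {
    assert_standard_residue(mutations$wild[i], sprintf("row %d wild residue", i))
    assert_standard_residue(mutations$mutant[i], sprintf("row %d mutant residue", i))
  }
  if (any(mutations$wild == mutations$mutant)) {
    stop_validation("not missense: wild == mutant")
  }
  seqs <- proteins[mutations$protein_id]
  too_far <- mutations$position > nchar(seqs)
  if (any(too_far)) {
    stop_validation(sprintf("position %d beyond sequence end of '%s' (row %d)",
                            mutations$position[which(too_far)[1]],
                            mutations$protein_id[which(too_far)[1]],
                            which(too_far)[1]))
  }
  at_pos <- substr(seqs, mutations$position, mutations$position)
  mismatch <- at_pos != mutations$wild
  if (any(mismatch)) {
    i <- which(mismatch)[1]
    stop_validation(sprintf(
      "wild-type residue mismatch at row %d: table says %s but %s position %d is %s",
      i, mutations$wild[i], mutations$protein_id[i], mutations$position[i], at_pos[i]))
  }
  key <- paste(mutations$protein_id, mutations$position,
               mutations$wild, mutations$mutant, sep = ":")
  if (anyDuplicated(key)) {
    stop_validation(sprintf("duplicate mutation record: %s", key[duplicated(key)][1]))
  }
  if (!"label" %in% names(mutations)) mutations$label <- NA_character_
  annotated <- attr(mutations, "annotated_features")
  if (is.null(annotated)) {
    annotated <- setdiff(names(mutations), c(MUTATION_COLUMNS, "label"))
  }
  structure(list(proteins = proteins,
                 mutations = mutations,
                 annotated = annotated),
            class = "mutation_dataset")
}

#' Stable per-mutation sample identifiers
#'
#' @param ds A `mutation_dataset`.
#' @return Character vector `protein:position:wild>mutant`, one per mutation.
#' @export
mutation_ids <- function(ds) {
  m <- ds$mutations
  sprintf("%s:%d:%s>%s", m$protein_id, m$position, m$wild, m$mutant)
}

#' Class labels of a mutation dataset
#'
#' @param ds A `mutation_dataset`.
#' @return Factor with levels `driver`, `passenger` (NA where unlabeled).
#' @export
mutation_labels <- function(ds) {
  factor(ds$mutations$label, levels = c("driver", "passenger"))
}

#' @export
print.mutation_dataset <- function(x, ...) {
  lab <- table(factor(x$mutations$label, levels = c("driver", "passenger")),
               useNA = "ifany")
  cat(sprintf("mutation_dataset: %d proteins, %d mutations (%d driver / %d passenger), %d annotated feature(s)\n",
              length(x$proteins), nrow(x$mutations),
              lab[["driver"]], lab[["passenger"]], length(x$annotated)))
  invisible(x)
}

# Coerce/validate labels into the canonical driver/passenger factor.
normalize_labels <- function(labels) {
  f <- factor(as.character(labels), levels = c("driver", "passenger"))
  if (anyNA(f)) stop_validation("labels must all be 'driver' or 'passenger'")
  f
}

# Subset a mutation_dataset by mutation row index, keeping all proteins.
subset_dataset <- function(ds, idx) {
  m <- ds$mutations[idx, , drop = FALSE]
  attr(m, "annotated_features") <- ds$annotated
  rownames(m) <- NULL
  structure(list(proteins = ds$proteins, mutations = m, annotated = ds$annotated),
            class = "mutation_dataset")
}
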