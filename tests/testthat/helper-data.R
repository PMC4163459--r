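# Small in-code builders shared across test files.

toy_proteins <- function() {
  c(p1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
    p2 = "ACDEFGHIKLMNPQRSTVWY")
}

toy_mutations <- function() {
  m <- data.frame(protein_id = c("p1", "p1", "p2"),
                  position = c(3L, 10L, 5L),
                  wild = c("T", "R", "F"),
                  mutant = c("A", "H", "L"),
                  label = c("driver", "passenger", "driver"),
                  dom_feat = c(1, 0, NA),
                  cons_score = c(0.9, NA, 0.2),
                  stringsAsFactors = FALSE)
  attr(m, "annotated_features") <- c("dom_feat", "cons_score")
  m
}

toy_dataset <- function() {
  mutation_dataset(toy_proteins(), toy_mutations())
}

# a labeled mechanistic dataset small enough for fast extractor fits
small_sim <- function(seed = 1, effect = 2, n = 50,
                      channels = c("aarc", "ssm", "af")) {
  simulate_dataset(sim_config(n_proteins = 10, seq_len_range = c(60, 100),
                              n_driver = n, n_passenger = n,
                              informative_channels = channels,
                              effect_size = effect, seed = seed))
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_temp_tsv <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  path
}
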