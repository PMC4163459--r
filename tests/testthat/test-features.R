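test_that("gram counts match a hand count and conserve sequence length", {
  v <- gram_counts("AAG")
  expect_length(v, 436L)
  expect_equal(unname(v["g2.AA"]), 1)
  expect_equal(unname(v["g2.AG"]), 1)
  expect_equal(sum(v[1:400]), 2)
  # A, A, G all belong to 6-letter group 4
  expect_equal(unname(v["g6.4.4"]), 2)

  set.seed(7)
  for (i in 1:10) {
    L <- sample(5:80, 1)
    s <- paste(sample(drimm:::AA20, L, replace = TRUE), collapse = "")
    g <- gram_counts(s)
    expect_equal(sum(g[1:400]), L - 1)
    expect_equal(sum(g[401:436]), L - 1)
  }
  expect_error(gram_counts("A"), class = "drimm_validation_error")
  expect_error(gram_counts("ACXDE"), "X", class = "drimm_validation_error")
})

test_that("six-letter alphabet is total with the fixed group sizes", {
  groups <- six_letter_alphabet()
  expect_setequal(names(groups), drimm:::AA20)
  expect_equal(as.integer(table(groups)), c(4L, 3L, 1L, 5L, 4L, 3L))
  expect_equal(unname(groups[c("D", "H", "C", "S", "M", "F")]), 1:6)
})

test_that("AARC encoding is the wild-minus-mutant property difference", {
  ds <- toy_dataset()
  vals <- setNames(rep(1, 20), drimm:::AA20)
  vals["A"] <- 2; vals["V"] <- 5
  toy <- property_scale("toy", vals)
  proteins <- c(q = "AVAV")
  muts <- data.frame(protein_id = "q", position = 1L, wild = "A", mutant = "V")
  av <- mutation_dataset(proteins, muts)
  expect_equal(unname(encode_aarc(av, list(toy))[1, 1]), -3)

  # equal-property scale gives 0 everywhere; default set gives 15 columns
  flat <- property_scale("flat", setNames(rep(1.5, 20), drimm:::AA20))
  expect_true(all(encode_aarc(ds, list(flat)) == 0))
  full <- encode_aarc(ds)
  expect_equal(ncol(full), 15L)

  # antisymmetry: swapping wild and mutant negates every component
  # (swapped rows would not match the sequence, so evaluate the definition
  # directly instead of constructing a reversed dataset)
  m <- ds$mutations
  fwd <- encode_aarc(ds)
  bwd <- vapply(default_property_scales(),
                function(sc) unclass(sc)[m$mutant] - unclass(sc)[m$wild],
                numeric(nrow(m)))
  expect_equal(unname(fwd), -unname(bwd), tolerance = 1e-12)
})

test_that("SSM encoding is the (wild, mutant) matrix element", {
  offdiag <- matrix(-1, 20, 20, dimnames = list(drimm:::AA20, drimm:::AA20))
  diag(offdiag) <- 0
  toy1 <- substitution_matrix("uniform", offdiag)
  m2 <- offdiag
  m2["D", "E"] <- 7
  toy2 <- substitution_matrix("spiked", m2)

  proteins <- c(q = "ADE")
  muts <- data.frame(protein_id = "q", position = 2L, wild = "D", mutant = "E")
  dsq <- mutation_dataset(proteins, muts)
  enc <- encode_ssm(dsq, list(toy1, toy2))
  expect_equal(unname(enc[1, ]), c(-1, 7))
  expect_equal(ncol(encode_ssm(toy_dataset())), 51L)
})

test_that("bundled default tables have the documented shape", {
  scales <- default_property_scales()
  expect_length(scales, 15L)
  expect_true(all(vapply(scales, function(s) all(is.finite(s)), logical(1))))
  mats <- default_substitution_matrices()
  expect_length(mats, 51L)
  expect_true(all(vapply(mats, function(m) all(dim(m) == c(20, 20)), logical(1))))
  # log-odds matrices are not derived duplicates of each other
  expect_length(unique(names(mats)), 51L)
})

test_that("scale and matrix TSVs round-trip", {
  sc <- default_property_scales()[[1]]
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_property_scale(sc, p1)
  back <- read_property_scale(p1, name = attr(sc, "name"))
  expect_equal(unclass(back), unclass(sc), tolerance = 1e-12,
               ignore_attr = TRUE)

  mat <- default_substitution_matrices()[["BLOSUM62"]]
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_substitution_matrix(mat, p2)
  back2 <- read_substitution_matrix(p2, name = "BLOSUM62")
  expect_equal(unclass(back2), unclass(mat), ignore_attr = TRUE)
})

test_that("lcc equals an independent Pearson computation on random vectors", {
  expect_equal(lcc(c(1, 2, 3, 5), c(1, 2, 3, 5)), 1)
  expect_equal(lcc(c(1, 2, 3, 5), 10 - 2 * c(1, 2, 3, 5)), -1)
  set.seed(11)
  for (i in 1:100) {
    x <- runif(436)
    y <- runif(436)
    expect_lt(abs(lcc(x, y) - oracle_pearson(x, y)), 1e-12)
  }
  expect_warning(out <- lcc(rep(2, 436), runif(436)), "zero-variance")
  expect_true(is.na(out))
})

test_that("PSS reducer selects the planted gram column and exactly top_k indices", {
  set.seed(5)
  n <- 100
  grams <- matrix(rnorm(n * 436), n, 436)
  labels <- rep(c("driver", "passenger"), each = n / 2)
  grams[labels == "driver", 7] <- grams[labels == "driver", 7] + 5
  rownames(grams) <- sprintf("s%03d", 1:n)
  red <- fit_pss_reducer(grams, labels, top_k = 30)
  expect_equal(red$selected[1], 7L)
  expect_length(red$selected, 30L)
  expect_false(anyDuplicated(red$selected) > 0)
  expect_true(all(red$selected >= 1 & red$selected <= 436))
  expect_identical(red$fitted_ids, rownames(grams))

  expect_error(fit_pss_reducer(grams, rep("driver", n)),
               class = "drimm_validation_error")
  const <- matrix(1, 20, 436, dimnames = list(sprintf("c%02d", 1:20), NULL))
  expect_warning(zr <- fit_pss_reducer(const, rep(c("driver", "passenger"), 10),
                                       top_k = 5),
                 "zero")
  expect_equal(zr$selected, 1:5)
  expect_error(fit_pss_reducer(const, rep(c("driver", "passenger"), 10),
                               top_k = 5, on_constant = "error"),
               class = "drimm_validation_error")
})

test_that("PSS features are sequence-level, 31 wide, and need a fitted reducer", {
  sim <- small_sim(seed = 3)
  ds <- sim$dataset
  ex <- fit_feature_extractor(ds)
  pss <- encode_pss(ds, ex$reducer)
  expect_equal(ncol(pss), 31L)
  expect_equal(colnames(pss)[31], "pss.lcc")

  same_prot <- which(duplicated(ds$mutations$protein_id) |
                       duplicated(ds$mutations$protein_id, fromLast = TRUE))
  pid <- ds$mutations$protein_id[same_prot[1]]
  rows <- which(ds$mutations$protein_id == pid)
  expect_equal(unname(pss[rows[1], ]), unname(pss[rows[2], ]))

  expect_error(encode_pss(ds, list(not = "fitted")),
               class = "drimm_validation_error")
})

test_that("AF encoding respects the schema, imputes missing values, rejects bad binaries", {
  sim <- small_sim(seed = 9)
  af <- suppressMessages(encode_af(sim$dataset))
  expect_equal(ncol(af), 29L)
  expect_false(anyNA(af))

  # all annotated values missing: defaults filled, imputations counted
  proteins <- c(q = "ACDEFG")
  muts <- data.frame(protein_id = "q", position = 1L, wild = "A", mutant = "C")
  bare <- mutation_dataset(proteins, muts)
  msgs <- capture_messages(out <- encode_af(bare))
  expect_match(msgs, "imputed 29", all = FALSE)
  expect_equal(sum(attr(out, "imputed")), 29L)

  bad <- muts
  bad$af.bin01 <- 2
  attr(bad, "annotated_features") <- "af.bin01"
  bad_ds <- mutation_dataset(proteins, bad)
  expect_error(suppressMessages(encode_af(bad_ds)), "af.bin01",
               class = "drimm_validation_error")
})

test_that("assembled feature space is 126 wide with stable provenance, 97 without AF", {
  sim <- small_sim(seed = 21)
  ex <- fit_feature_extractor(sim$dataset)
  fm <- suppressMessages(assemble_features(sim$dataset, ex))
  expect_equal(ncol(fm), 126L)
  expect_equal(as.integer(table(provenance(fm))[c("AARC", "SSM", "PSS", "AF")]),
               c(15L, 51L, 31L, 29L))
  expect_false(anyDuplicated(colnames(fm)) > 0)

  cfg <- feature_config(af_schema_df = NULL)
  ex97 <- fit_feature_extractor(sim$dataset, cfg)
  fm97 <- assemble_features(sim$dataset, ex97)
  expect_equal(ncol(fm97), 97L)

  # determinism: same dataset + config twice is bitwise identical
  ex2 <- fit_feature_extractor(sim$dataset)
  fm2 <- suppressMessages(assemble_features(sim$dataset, ex2))
  expect_identical(fm, fm2)
})

test_that("PSS reduction is train-only: refitting with test data would change it", {
  train <- small_sim(seed = 31, effect = 0, n = 30)$dataset
  # adversarial extra proteins whose grams would shift the DX ranking
  extra <- simulate_dataset(sim_config(n_proteins = 8, seq_len_range = c(60, 100),
                                       n_driver = 30, n_passenger = 30,
                                       informative_channels = "pss",
                                       effect_size = 4, seed = 77))$dataset
  extra$proteins <- setNames(extra$proteins, paste0("x", names(extra$proteins)))
  extra$mutations$protein_id <- paste0("x", extra$mutations$protein_id)

  ex_train <- fit_feature_extractor(train)
  combined <- mutation_dataset(
    c(train$proteins, extra$proteins),
    {
      m <- rbind(train$mutations[names(extra$mutations)], extra$mutations)
      attr(m, "annotated_features") <- train$annotated
      m
    })
  ex_both <- fit_feature_extractor(combined)
  expect_false(identical(ex_train$reducer$selected, ex_both$reducer$selected))

  # and the pipeline never refits on test: extractor keeps only train ids
  expect_identical(ex_train$reducer$fitted_ids, mutation_ids(train))
  test_ds <- small_sim(seed = 32, effect = 0, n = 10)$dataset
  expect_length(intersect(mutation_ids(test_ds), ex_train$reducer$fitted_ids), 0L)
})

test_that("feature matrix TSV + provenance sidecar round-trips", {
  sim <- small_sim(seed = 41, n = 15)
  ex <- fit_feature_extractor(sim$dataset)
  fm <- suppressMessages(assemble_features(sim$dataset, ex))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(fm, path, labels = mutation_labels(sim$dataset))
  back <- read_feature_matrix(path)
  expect_equal(unname(back$features), unname(fm), tolerance = 1e-9)
  expect_equal(colnames(back$features), colnames(fm))
  expect_equal(unname(attr(back$features, "provenance")),
               unname(provenance(fm)))
  expect_equal(back$labels, as.character(mutation_labels(sim$dataset)))
})
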