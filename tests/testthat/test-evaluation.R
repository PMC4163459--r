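# a stub model type exercising the generic predict contract: always driver
constant_driver_model <- function() {
  structure(list(), class = "constant_driver")
}

test_that("cross-validation is exact on separable data and deterministic", {
  sim <- simulate_feature_matrix(30, 4, 4, 10, seed = 18)
  rep1 <- cross_validate(sim$x, sim$labels, rotation_forest_trainer(),
                         folds = 5, repeats = 3, seed = 19)
  expect_true(all(abs(rep1$metrics$mean - 1) < 1e-12))
  expect_true(all(rep1$metrics$variance < 1e-12))
  expect_equal(nrow(rep1$per_repeat), 3L)

  rep2 <- cross_validate(sim$x, sim$labels, rotation_forest_trainer(),
                         folds = 5, repeats = 3, seed = 19)
  expect_identical(rep1$metrics, rep2$metrics)
  expect_identical(rep1$per_repeat, rep2$per_repeat)
})

test_that("cross-validation refuses folds larger than the smaller class", {
  sim <- simulate_feature_matrix(3, 4, 2, 2, seed = 20)
  expect_error(cross_validate(sim$x, sim$labels, decision_tree_trainer(),
                              folds = 5, repeats = 1),
               class = "drimm_validation_error")
})

test_that("roc_area matches closed forms, the all-pairs oracle, and its complement law", {
  labels <- c("driver", "driver", "passenger", "passenger")
  expect_equal(roc_area(c(0.9, 0.8, 0.3, 0.1), labels), 1)
  expect_equal(roc_area(c(0.1, 0.2, 0.8, 0.9), labels), 0)
  expect_error(roc_area(1:3, rep("driver", 3)), class = "drimm_validation_error")

  set.seed(21)
  for (i in 1:30) {
    n <- sample(6:20, 1)
    lab <- sample(rep(c("driver", "passenger"), length.out = n))
    sc <- sample(1:6, n, replace = TRUE)  # discrete scores force ties
    expect_equal(roc_area(sc, lab), oracle_auc(sc, lab))
  }

  # tie-free complement property
  for (i in 1:10) {
    lab <- sample(rep(c("driver", "passenger"), 6))
    sc <- rnorm(12)
    expect_equal(roc_area(sc, lab) + roc_area(-sc, lab), 1, tolerance = 1e-12)
  }
})

test_that("roc_area agrees with an established AUC implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  lab <- sample(rep(c("driver", "passenger"), 25))
  sc <- rnorm(50)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = lab, predictor = sc, levels = c("passenger", "driver"),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_area(sc, lab), ref, tolerance = 1e-12)
})

test_that("holdout evaluation of a constant-positive classifier", {
  registerS3method("predict_proba", "constant_driver",
                   function(model, x) {
                     matrix(rep(c(1, 0), each = nrow(x)), ncol = 2,
                            dimnames = list(rownames(x), c("driver", "passenger")))
                   },
                   envir = asNamespace("drimm"))
  x <- matrix(rnorm(50), 50, 1, dimnames = list(sprintf("t%02d", 1:50), "f"))
  labels <- rep(c("driver", "passenger"), c(10, 40))
  rep <- evaluate_on_holdout(constant_driver_model(), x, labels)
  cm <- rep$confusion
  expect_equal(c(cm$tp, cm$fp, cm$tn, cm$fn), c(10, 40, 0, 0))
  expect_equal(rep$metrics$recall, 1)
  expect_equal(rep$metrics$precision, 0.2)
  expect_error(evaluate_on_holdout(constant_driver_model(),
                                   x[0, , drop = FALSE], character(0)),
               class = "drimm_validation_error")
})

test_that("the leakage guard refuses test samples seen by the PSS reducer", {
  sim <- small_sim(seed = 51, n = 25)
  ds <- sim$dataset
  ex <- fit_feature_extractor(ds)
  fm <- suppressMessages(assemble_features(ds, ex))
  labels <- mutation_labels(ds)
  model <- fit_rotation_forest(fm, labels, rotation_spec(n_trees = 2))
  expect_error(evaluate_on_holdout(model, fm, labels, extractor = ex),
               "leakage", class = "drimm_validation_error")

  # a genuinely disjoint test set passes the guard
  test_sim <- small_sim(seed = 52, n = 10)
  test_fm <- suppressMessages(assemble_features(test_sim$dataset, ex))
  rep <- evaluate_on_holdout(model, test_fm, mutation_labels(test_sim$dataset),
                             extractor = ex)
  expect_s3_class(rep, "holdout_report")
})

test_that("reports recompute from stored confusion counts without drift", {
  cm <- confusion_matrix(892, 597, 3942, 221)
  rep <- structure(list(confusion = cm, metrics = metrics_from_confusion(cm),
                        n_test = 5652), class = "holdout_report")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_holdout_report(rep, path)
  tab <- read.delim(path)
  expect_equal(as.integer(tab[1, c("TP", "FP", "TN", "FN")]),
               c(892L, 597L, 3942L, 221L))
  refreshed <- metrics_from_confusion(confusion_matrix(tab$TP, tab$FP, tab$TN, tab$FN))
  expect_equal(refreshed, rep$metrics, tolerance = 1e-12)
  expect_equal(tab$accuracy, 85.53)
})

test_that("CV report files round-trip through the writers", {
  sim <- simulate_feature_matrix(20, 4, 2, 3, seed = 23)
  rep <- cross_validate(sim$x, sim$labels, decision_tree_trainer(),
                        folds = 4, repeats = 2, seed = 24)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cv_report(rep, path)
  tab <- read.delim(path)
  expect_equal(tab$metric, rep$metrics$metric)
  expect_equal(tab$mean, rep$metrics$mean, tolerance = 1e-9)
  j <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(j$folds, 4)
  expect_equal(j$variance_over, "repeats")
})
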