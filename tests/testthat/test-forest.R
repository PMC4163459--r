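# two well-separated Gaussian blobs, linearly separable
separable_blobs <- function(n_per_class = 100, p = 4, gap = 8, seed = 1) {
  set.seed(seed)
  labels <- factor(rep(c("driver", "passenger"), each = n_per_class),
                   levels = c("driver", "passenger"))
  x <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p,
              dimnames = list(NULL, paste0("b", seq_len(p))))
  x[labels == "driver", ] <- x[labels == "driver", ] + gap
  list(x = x, labels = labels)
}

test_that("every per-group rotation block is orthonormal on random data", {
  sim <- simulate_feature_matrix(40, 13, 3, 1, seed = 3)
  model <- fit_rotation_forest(sim$x, sim$labels,
                               rotation_spec(n_trees = 6, seed = 9))
  for (R in model$rotations) {
    # block-diagonal of orthonormal blocks => whole rotation orthonormal
    expect_lt(max(abs(t(R) %*% R - diag(ncol(R)))), 1e-8)
  }
})

test_that("subset_size 1 reduces every block to a sign flip", {
  sim <- simulate_feature_matrix(30, 5, 2, 2, seed = 4)
  model <- fit_rotation_forest(sim$x, sim$labels,
                               rotation_spec(n_trees = 3, subset_size = 1, seed = 2))
  for (R in model$rotations) {
    expect_true(all(abs(abs(diag(R)) - 1) < 1e-12))
    expect_true(all(R[row(R) != col(R)] == 0))
  }
})

test_that("fitting is deterministic given the spec seed", {
  sim <- simulate_feature_matrix(50, 10, 3, 2, seed = 6)
  held <- simulate_feature_matrix(30, 10, 3, 2, seed = 7)
  m1 <- fit_rotation_forest(sim$x, sim$labels, rotation_spec(seed = 123))
  m2 <- fit_rotation_forest(sim$x, sim$labels, rotation_spec(seed = 123))
  expect_identical(predict_proba(m1, held$x), predict_proba(m2, held$x))
})

test_that("probabilities normalize and training accuracy is perfect on separable blobs", {
  blobs <- separable_blobs(seed = 8)
  model <- fit_rotation_forest(blobs$x, blobs$labels)
  pr <- predict_proba(model, blobs$x)
  expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-12)
  expect_equal(mean(predict(model, blobs$x) == blobs$labels), 1)
})

test_that("a single-tree forest equals a CART tree on the rotated data", {
  blobs <- separable_blobs(n_per_class = 60, p = 6, gap = 3, seed = 10)
  model <- fit_rotation_forest(blobs$x, blobs$labels,
                               rotation_spec(n_trees = 1, seed = 5))
  rotated <- blobs$x %*% model$rotations[[1]]
  df <- as.data.frame(rotated)
  names(df) <- paste0("r", seq_len(ncol(df)))
  df$.y <- blobs$labels
  ref <- rpart::rpart(.y ~ ., df, method = "class",
                      control = rpart::rpart.control(cp = 0, xval = 0,
                                                     minsplit = 4, minbucket = 2))
  ref_pred <- predict(ref, df, type = "class")
  expect_identical(as.character(predict(model, blobs$x)),
                   as.character(ref_pred))
})

test_that("prediction refuses mismatched feature names, naming the divergence", {
  sim <- simulate_feature_matrix(30, 5, 2, 2, seed = 11)
  model <- fit_rotation_forest(sim$x, sim$labels, rotation_spec(n_trees = 2))
  bad <- sim$x
  colnames(bad)[2] <- "intruder"
  expect_error(predict_proba(model, bad), "intruder",
               class = "drimm_validation_error")
  expect_error(predict_proba(model, sim$x[, 1:3]), "expected",
               class = "drimm_validation_error")
})

test_that("ties in class probability resolve to the driver class", {
  # classes with identical feature values force 50/50 leaves
  x <- matrix(rep(c(1, 2), each = 8), ncol = 1, dimnames = list(NULL, "f"))
  labels <- rep(c("driver", "passenger"), 8)
  model <- fit_rotation_forest(x, labels, rotation_spec(n_trees = 1, subset_size = 1))
  pr <- predict_proba(model, x)
  expect_true(all(abs(pr[, "driver"] - 0.5) < 1e-12))
  expect_true(all(predict(model, x) == "driver"))
})

test_that("models survive a save/load round trip and refuse foreign archives", {
  sim <- simulate_feature_matrix(40, 8, 3, 2, seed = 12)
  held <- simulate_feature_matrix(20, 8, 3, 2, seed = 13)
  model <- fit_rotation_forest(sim$x, sim$labels, rotation_spec(n_trees = 4))
  path <- withr::local_tempfile(fileext = ".rds")
  save_rotation_forest(model, path)
  back <- load_rotation_forest(path)
  expect_identical(predict_proba(back, held$x), predict_proba(model, held$x))

  tampered <- model
  tampered$format <- 99L
  p2 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(tampered, p2)
  expect_error(load_rotation_forest(p2), "format", class = "drimm_format_error")
})

test_that("CV accuracy is insensitive to a global orthonormal rotation of the inputs", {
  sim <- simulate_feature_matrix(60, 6, 3, 1.5, seed = 14)
  set.seed(15)
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  xr <- sim$x %*% Q
  colnames(xr) <- colnames(sim$x)
  a0 <- cv_accuracy(cross_validate(sim$x, sim$labels, rotation_forest_trainer(),
                                   folds = 5, repeats = 3, seed = 16))
  a1 <- cv_accuracy(cross_validate(xr, sim$labels, rotation_forest_trainer(),
                                   folds = 5, repeats = 3, seed = 16))
  expect_lt(abs(a0 - a1), 0.1)
})

test_that("rotation forest beats a single tree on DX-selected features (paired sign test)", {
  eff <- 4 / sqrt(5)
  wins <- 0L
  losses <- 0L
  for (s in 1:20) {
    sim <- simulate_feature_matrix(60, 30, 5, eff, seed = 100 + s)
    r <- rank_dx(sim$x, sim$labels)
    xs <- sim$x[, r$feature[1:8], drop = FALSE]
    a_rf <- cv_accuracy(cross_validate(xs, sim$labels, rotation_forest_trainer(),
                                       folds = 5, repeats = 2, seed = s))
    a_tr <- cv_accuracy(cross_validate(xs, sim$labels, decision_tree_trainer(),
                                       folds = 5, repeats = 2, seed = s))
    if (a_rf > a_tr) wins <- wins + 1L else if (a_rf < a_tr) losses <- losses + 1L
  }
  expect_lt(binom.test(wins, wins + losses, alternative = "greater")$p.value, 0.05)
})
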