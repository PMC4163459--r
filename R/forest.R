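#' Rotation-forest hyperparameters
#'
#' Pinned to the canonical published defaults of the algorithm: 10 trees,
#' random feature groups of 3, per-group principal axes fitted on a
#' bootstrap of 50% of the instances of a random nonempty class subset, all
#' components retained, and an unpruned CART base tree with Gini splitting.
#'
#' @param n_trees Ensemble size (default 10).
#' @param subset_size Features per rotation group (default 3; the last group
#'   of a tree may be smaller).
#' @param sample_fraction Fraction of the class-subset instances bootstrapped
#'   for each per-group principal-axis fit (default 0.5).
#' @param seed RNG seed controlling all sampling in the fit.
#' @return Object of class `rotation_spec`.
#' @export
rotation_spec <- function(n_trees = 10, subset_size = 3,
                          sample_fraction = 0.5, seed = 1) {
  if (n_trees < 1) stop_config("n_trees must be >= 1")
  if (subset_size < 1) stop_config("subset_size must be >= 1")
  if (sample_fraction <= 0 || sample_fraction > 1) {
    stop_config("sample_fraction must be in (0, 1]")
  }
  structure(list(n_trees = as.integer(n_trees),
                 subset_size = as.integer(subset_size),
                 sample_fraction = sample_fraction,
                 seed = as.integer(seed)),
            class = "rotation_spec")
}

ROTATION_FOREST_FORMAT <- 1L

# Orthonormal principal axes of a data slice via the eigendecomposition of
# its covariance (always a full p x p orthonormal basis, even for rank-
# deficient slices, unlike prcomp which drops trailing components). Column
# signs are fixed deterministically (largest-magnitude loading positive).
principal_axes <- function(slice) {
  C <- cov(slice)
  if (any(!is.finite(C))) return(NULL)
  ev <- eigen(C, symmetric = TRUE)$vectors
  for (j in seq_len(ncol(ev))) {
    k <- which.max(abs(ev[, j]))
    if (ev[k, j] < 0) ev[, j] <- -ev[, j]
  }
  ev
}

#' Fit a rotation forest
#'
#' For each tree: features are randomly partitioned into groups of
#' `subset_size`; for each group a random nonempty subset of the classes is
#' drawn, a bootstrap of `sample_fraction` of those instances taken, and the
#' principal axes of that slice (all components) form the group's rotation
#' block; the blocks assemble into a block-diagonal rotation and a CART tree
#' is trained on the fully rotated training matrix. Diversity comes from the
#' per-tree random partitions and the sampled PCA fits. Deterministic given
#' the spec seed.
#'
#' @param x Numeric sample-by-feature matrix with column names; no missing
#'   values (impute upstream).
#' @param labels Driver/passenger labels, >= 2 samples per class.
#' @param spec A [rotation_spec()].
#' @return Object of class `rotation_forest` with per-tree rotations and
#'   fitted base trees.
#' @export
fit_rotation_forest <- function(x, labels, spec = rotation_spec()) {
  labels <- normalize_labels(labels)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (anyNA(x)) stop_validation("rotation forest requires complete data; impute first")
  if (min(table(labels)) < 2L) stop_validation("need >= 2 samples per class")
  p <- ncol(x)
  n <- nrow(x)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  trees <- vector("list", spec$n_trees)
  rotations <- vector("list", spec$n_trees)
  for (t in seq_len(spec$n_trees)) {
    perm <- sample.int(p)
    groups <- split(perm, ceiling(seq_along(perm) / spec$subset_size))
    R <- matrix(0, p, p)
    for (g in groups) {
      # nonempty random class subset: {driver}, {passenger}, or both
      pick <- switch(sample.int(3L, 1L),
                     "driver", "passenger", c("driver", "passenger"))
      rows <- which(labels %in% pick)
      m <- max(2L, round(spec$sample_fraction * length(rows)))
      block <- NULL
      for (attempt in 1:2) {
        boot <- sample(rows, m, replace = TRUE)
        if (length(unique(boot)) >= 2L) {
          block <- principal_axes(x[boot, g, drop = FALSE])
          if (!is.null(block)) break
        }
      }
      if (is.null(block)) {
        warning("degenerate PCA slice; falling back to identity rotation block")
        block <- diag(length(g))
      }
      R[g, g] <- block
    }
    rotated <- x %*% R
    df <- as.data.frame(rotated)
    names(df) <- paste0("r", seq_len(p))
    df$.y <- labels
    trees[[t]] <- rpart::rpart(.y ~ ., data = df, method = "class",
                               control = rpart::rpart.control(
                                 cp = 0, xval = 0, minsplit = 4, minbucket = 2))
    rotations[[t]] <- R
  }
  structure(list(spec = spec,
                 rotations = rotations,
                 trees = trees,
                 feature_names = colnames(x),
                 levels = c("driver", "passenger"),
                 n_train = n,
                 format = ROTATION_FOREST_FORMAT),
            class = "rotation_forest")
}

# Preserve the caller's RNG state so fitting is a pure function of the spec
# seed without clobbering an enclosing simulation's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}

check_feature_names <- function(model, x) {
  nms <- colnames(x)
  if (is.null(nms) || length(nms) != length(model$feature_names) ||
      any(nms != model$feature_names)) {
    diverge <- if (is.null(nms)) {
      "(no column names)"
    } else {
      i <- which(nms[seq_len(min(length(nms), length(model$feature_names)))] !=
                   model$feature_names[seq_len(min(length(nms), length(model$feature_names)))])
      if (length(i) > 0) {
        sprintf("first divergent feature: got '%s', expected '%s'",
                nms[i[1]], model$feature_names[i[1]])
      } else {
        sprintf("got %d features, expected %d", length(nms), length(model$feature_names))
      }
    }
    stop_validation(paste("feature names do not match the training order;", diverge))
  }
}

#' Class probabilities from a rotation forest
#'
#' Mean of the per-tree leaf class distributions, each tree seeing the input
#' through its own rotation. Rows sum to 1.
#'
#' @param model A fitted [fit_rotation_forest()] model.
#' @param x Feature matrix whose columns match the training order exactly.
#' @return Matrix n x 2 with columns `driver`, `passenger`.
#' @export
predict_proba <- function(model, x) {
  UseMethod("predict_proba")
}

#' @export
predict_proba.rotation_forest <- function(model, x) {
  x <- as.matrix(x)
  check_feature_names(model, x)
  p <- ncol(x)
  acc <- matrix(0, nrow(x), 2, dimnames = list(rownames(x), model$levels))
  for (t in seq_along(model$trees)) {
    rotated <- x %*% model$rotations[[t]]
    df <- as.data.frame(rotated)
    names(df) <- paste0("r", seq_len(p))
    pr <- predict(model$trees[[t]], newdata = df, type = "prob")
    # rpart may drop an absent class level; align explicitly
    for (lv in model$levels) {
      if (lv %in% colnames(pr)) acc[, lv] <- acc[, lv] + pr[, lv]
    }
  }
  acc / length(model$trees)
}

#' @export
predict.rotation_forest <- function(object, newdata, ...) {
  pr <- predict_proba(object, newdata)
  # tie -> positive (driver) class
  factor(ifelse(pr[, "driver"] >= pr[, "passenger"], "driver", "passenger"),
         levels = c("driver", "passenger"))
}

#' @export
print.rotation_forest <- function(x, ...) {
  cat(sprintf("rotation_forest: %d trees, groups of %d over %d features, trained on %d samples\n",
              length(x$trees), x$spec$subset_size, length(x$feature_names), x$n_train))
  invisible(x)
}

#' Persist / restore a rotation forest
#'
#' The archive is versioned; loading refuses an incompatible format version.
#'
#' @param model A `rotation_forest`.
#' @param path Destination file.
#' @return `path` invisibly (save); the model (load).
#' @export
save_rotation_forest <- function(model, path) {
  stopifnot(inherits(model, "rotation_forest"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_rotation_forest
#' @export
load_rotation_forest <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "rotation_forest") ||
      is.null(model$format) || model$format != ROTATION_FOREST_FORMAT) {
    stop_format(sprintf("'%s' is not a compatible rotation-forest archive (format %s)",
                        path, ROTATION_FOREST_FORMAT))
  }
  model
}
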