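# Trainers: a uniform fit/predict contract shared by the rotation forest and
# the pluggable comparison classifiers. A trainer is a list with elements
#   name          - character label used in reports
#   fit(x, y)     - returns an opaque fitted object
#   predict_proba(model, x) - n x 2 matrix with columns driver, passenger
# Anything honoring this contract can be handed to cross_validate() and
# ifs().

#' Rotation-forest trainer
#'
#' Wraps [fit_rotation_forest()] in the generic trainer contract used by
#' [cross_validate()] and [ifs()].
#'
#' @param spec A [rotation_spec()].
#' @return Trainer object (list with `name`, `fit`, `predict_proba`).
#' @export
rotation_forest_trainer <- function(spec = rotation_spec()) {
  list(name = "rotation_forest",
       fit = function(x, y) fit_rotation_forest(x, y, spec),
       predict_proba = function(model, x) predict_proba(model, x))
}

#' Single CART decision-tree trainer (comparison baseline)
#'
#' @param minsplit,cp rpart controls (defaults mirror the rotation forest's
#'   base tree).
#' @return Trainer object.
#' @export
decision_tree_trainer <- function(minsplit = 4, cp = 0) {
  list(name = "decision_tree",
       fit = function(x, y) {
         y <- normalize_labels(y)
         df <- as.data.frame(as.matrix(x))
         names(df) <- paste0("v", seq_len(ncol(df)))
         df$.y <- y
         rpart::rpart(.y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(cp = cp, xval = 0,
                                                     minsplit = minsplit,
                                                     minbucket = 2))
       },
       predict_proba = function(model, x) {
         df <- as.data.frame(as.matrix(x))
         names(df) <- paste0("v", seq_len(ncol(df)))
         pr <- predict(model, newdata = df, type = "prob")
         out <- matrix(0, nrow(df), 2, dimnames = list(rownames(x), c("driver", "passenger")))
         for (lv in colnames(pr)) out[, lv] <- pr[, lv]
         out
       })
}

#' Support-vector-machine trainer (comparison classifier)
#'
#' Wires a library SVM (e1071, a libsvm binding) into the trainer contract
#' for side-by-side comparisons; requires the suggested e1071 package.
#'
#' @param ... Passed to `e1071::svm` (kernel, cost, ...).
#' @return Trainer object.
#' @export
svm_trainer <- function(...) {
  if (!requireNamespace("e1071", quietly = TRUE)) {
    stop_config("svm_trainer requires the suggested package 'e1071'")
  }
  args <- list(...)
  list(name = "svm",
       fit = function(x, y) {
         y <- normalize_labels(y)
         do.call(e1071::svm, c(list(x = as.matrix(x), y = y, probability = TRUE), args))
       },
       predict_proba = function(model, x) {
         pred <- predict(model, as.matrix(x), probability = TRUE)
         pr <- attr(pred, "probabilities")
         out <- matrix(0, nrow(x), 2, dimnames = list(rownames(x), c("driver", "passenger")))
         for (lv in colnames(pr)) out[, lv] <- pr[, lv]
         out
       })
}
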