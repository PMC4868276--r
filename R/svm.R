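# RBF-SVM training (libsvm via e1071), feature scaling, grid search and
# cross-validation machinery.

#' Cost/gamma search lattice
#'
#' The default lattice follows the widely used exponential grid:
#' cost `2^(-5), 2^(-3), ..., 2^15` and gamma `2^(-15), 2^(-13), ..., 2^3`.
#'
#' @param cost Vector of cost values.
#' @param gamma Vector of gamma values.
#' @return A data frame with one row per lattice point.
#' @export
svm_grid <- function(cost = 2^seq(-5, 15, by = 2),
                     gamma = 2^seq(-15, 3, by = 2)) {
  expand.grid(cost = cost, gamma = gamma, KEEP.OUT.ATTRS = FALSE)
}

# Per-feature [-1, 1] scaling statistics from training data only.
scale_fit <- function(x) {
  list(min = apply(x, 2L, min), max = apply(x, 2L, max))
}

# Apply scaling; a feature constant in training maps to 0 everywhere.
scale_apply <- function(x, sc) {
  rng <- sc$max - sc$min
  const <- rng == 0
  rng[const] <- 1
  out <- sweep(sweep(x, 2L, sc$min), 2L, rng, "/") * 2 - 1
  out[, const] <- 0
  out
}

as_label_factor <- function(labels) {
  factor(labels, levels = c("negative", "positive"))
}

# Fit libsvm on pre-scaled data.  Decision values are re-oriented so that
# larger values always mean "positive".
fit_raw_svm <- function(x, y, cost, gamma) {
  e1071::svm(x, y, type = "C-classification", kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE)
}

predict_raw_svm <- function(fit, x) {
  if (nrow(x) == 0L) {
    return(list(label = character(0), decision = numeric(0)))
  }
  pred <- stats::predict(fit, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  sign_flip <- if (colnames(dv)[1] == "negative/positive") -1 else 1
  list(label = as.character(pred), decision = sign_flip * as.numeric(dv[, 1]))
}

# Pooled cross-validated accuracy of an RBF-SVM on the given feature
# columns, under a fixed fold plan.  Scaling statistics come from the
# training folds only.
cv_accuracy <- function(x, labels, fold, cost, gamma) {
  y <- as_label_factor(labels)
  correct <- 0L
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (length(unique(labels[tr])) < 2L) {
      stop("degenerate fold: a training fold contains a single class")
    }
    sc <- scale_fit(x[tr, , drop = FALSE])
    fit <- fit_raw_svm(scale_apply(x[tr, , drop = FALSE], sc), y[tr],
                       cost, gamma)
    pred <- predict_raw_svm(fit, scale_apply(x[!tr, , drop = FALSE], sc))
    correct <- correct + sum(pred$label == labels[!tr])
  }
  correct / length(labels)
}

# Out-of-fold decision values and predicted labels under a fixed fold plan.
cv_predict <- function(x, labels, fold, cost, gamma) {
  y <- as_label_factor(labels)
  decision <- numeric(length(labels))
  predicted <- character(length(labels))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    sc <- scale_fit(x[tr, , drop = FALSE])
    fit <- fit_raw_svm(scale_apply(x[tr, , drop = FALSE], sc), y[tr],
                       cost, gamma)
    pred <- predict_raw_svm(fit, scale_apply(x[!tr, , drop = FALSE], sc))
    decision[!tr] <- pred$decision
    predicted[!tr] <- pred$label
  }
  list(label = predicted, decision = decision)
}

#' Grid search for RBF-SVM hyperparameters
#'
#' Evaluates every lattice point by cross-validated accuracy under a fixed
#' fold plan and returns the maximiser; ties are broken toward the smaller
#' cost, then the smaller gamma.
#'
#' @param x Numeric feature matrix.
#' @param labels Character labels (`"positive"`/`"negative"`).
#' @param grid Lattice from [svm_grid()].
#' @param fold Integer fold assignment per sample.
#' @return A list with `cost`, `gamma`, `accuracy`, and the full
#'   `trace` (the grid with its accuracy column).
#' @export
grid_search <- function(x, labels, grid = svm_grid(), fold) {
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    cv_accuracy(x, labels, fold, grid$cost[i], grid$gamma[i])
  }, numeric(1))
  best <- which(acc == max(acc))
  best <- best[order(grid$cost[best], grid$gamma[best])][1]
  list(cost = grid$cost[best], gamma = grid$gamma[best],
       accuracy = acc[best], trace = cbind(grid, accuracy = acc))
}

#' Fit an RBF-SVM on selected features
#'
#' Scales every feature to `[-1, 1]` by its training minimum and maximum
#' (a constant feature maps to 0, also for unseen test values) and fits a
#' C-classification SVM with the radial kernel.
#'
#' @param x Numeric feature matrix (sites x features, named columns).
#' @param labels Character labels (`"positive"`/`"negative"`), both classes
#'   present with at least two samples each.
#' @param cost,gamma RBF-SVM hyperparameters.
#' @return An object of class `"acetyl_svm"`.
#' @export
svm_fit <- function(x, labels, cost, gamma) {
  if (length(unique(labels)) < 2L || min(table(labels)) < 2L) {
    stop("fitting requires at least two samples of each class")
  }
  sc <- scale_fit(x)
  fit <- fit_raw_svm(scale_apply(x, sc), as_label_factor(labels),
                     cost, gamma)
  structure(list(fit = fit, scaling = sc, features = colnames(x),
                 cost = cost, gamma = gamma),
            class = "acetyl_svm")
}

#' Predict with a fitted RBF-SVM
#'
#' Columns of `x` are aligned to the model's feature list by name (order
#' and extra columns are irrelevant); a missing feature column is an error.
#'
#' @param object An `"acetyl_svm"` fit.
#' @param x Numeric feature matrix whose columns include the model's
#'   features.
#' @param ... Unused.
#' @return A data frame with columns `label` and `decision` (larger
#'   decision values mean more positive).
#' @export
predict.acetyl_svm <- function(object, x, ...) {
  missing <- setdiff(object$features, colnames(x))
  if (length(missing) > 0L) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  }
  x <- x[, object$features, drop = FALSE]
  pred <- predict_raw_svm(object$fit, scale_apply(x, object$scaling))
  data.frame(label = pred$label, decision = pred$decision,
             stringsAsFactors = FALSE)
}
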