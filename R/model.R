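# The central fitting function and its S3 methods.

#' Fit a lysine-acetylation site predictor
#'
#' Runs the full training pipeline: encodes the requested feature subtypes
#' over sliding windows of radius `L`, ranks every subtype's features by
#' absolute Pearson correlation with the class label, greedily selects
#' features per subtype under 5-fold cross-validated RBF-SVM accuracy
#' (hyperparameters tuned by grid search once per subtype, then once more
#' for the combined set), and fits the final SVM on the selected features.
#' Cross-validated performance (MCC, ACC, SEN, SPE, PRE, AUC and the ROC
#' curve) is computed from pooled out-of-fold predictions under the same
#' fold plan.
#'
#' If `sites` holds only positive sites, balanced negatives are sampled
#' from the non-annotated lysines of the same proteins at `ratio` negatives
#' per positive.
#'
#' @param proteins Named list of protein records from [read_fasta()].
#' @param sites Site data frame (`protein_id`, `position`, `label`).
#' @param profiles Optional named list of residue profiles from
#'   [parse_profiles()]; required for the profile subtypes.
#' @param L Window radius (default 6: the optimal window length 13).
#' @param subtypes Feature subtypes to use (default: sequence subtypes,
#'   plus profile subtypes when `profiles` is given).
#' @param ratio Negatives per positive when sampling is needed.
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Seed for fold assignment and negative sampling.
#' @param grid Hyperparameter lattice (default: a coarse 5 x 5 exponential
#'   lattice suitable for desk-scale data; see [svm_grid()] for the full
#'   published lattice).
#' @param select Run per-subtype feature selection (default `TRUE`; when
#'   `FALSE` all encoded features are used).
#' @param max_evaluations Per-subtype cap on stepwise candidate
#'   evaluations (default unlimited).
#' @param ... Encoder parameters forwarded to [encode_features()].
#' @return An object of class `"acetyl_model"`.
#' @export
acetyl_fit <- function(proteins, sites, profiles = NULL, L = 6L,
                       subtypes = NULL, ratio = 1, folds = 5L, seed = 1L,
                       grid = svm_grid(cost = 2^seq(-3, 5, 2),
                                       gamma = 2^seq(-9, -1, 2)),
                       select = TRUE, max_evaluations = Inf, ...) {
  sites <- validate_sites(sites, proteins)
  if (!any(sites$label == "negative")) {
    negatives <- sample_negatives(proteins, sites[sites$label == "positive", ],
                                  ratio = ratio, seed = seed)
    sites <- rbind(sites[sites$label == "positive", ], negatives)
  }
  sites <- sites[sites$label %in% c("positive", "negative"), ]
  if (length(unique(sites$label)) < 2L) {
    stop("training requires both positive and negative sites")
  }
  config <- list(L = L, subtypes = subtypes, ratio = ratio, folds = folds,
                 seed = seed, grid = grid, select = select,
                 max_evaluations = max_evaluations)
  fm <- encode_features(proteins, sites, profiles = profiles, L = L,
                        subtypes = subtypes, ...)
  labels <- attr(fm, "labels")
  fold <- stratified_folds(labels, k = folds, seed = seed)

  if (select) {
    sel <- select_features(fm, fold, grid = grid,
                           max_evaluations = max_evaluations)
    selection <- assemble_final_set(sel$results)
    subtype_tuning <- sel$tuning
  } else {
    subtype <- attr(fm, "subtype")
    selection <- structure(
      list(features = colnames(fm),
           per_subtype = lapply(split(colnames(fm), subtype), function(f)
             list(features = f, trajectory = numeric(0))),
           counts = vapply(split(colnames(fm), subtype), length, integer(1))),
      class = "selection_result")
    subtype_tuning <- NULL
  }

  x_sel <- unclass(fm)[, selection$features, drop = FALSE]
  final <- grid_search(x_sel, labels, grid = grid, fold = fold)
  oof <- cv_predict(x_sel, labels, fold, final$cost, final$gamma)
  cv <- eval_report(labels, oof$label, oof$decision)
  svm <- svm_fit(x_sel, labels, final$cost, final$gamma)

  structure(list(svm = svm, selection = selection,
                 subtype_tuning = subtype_tuning,
                 cost = final$cost, gamma = final$gamma,
                 cv = cv, fold = fold, seed = seed, L = L,
                 subtypes = unique(attr(fm, "subtype")),
                 knn_ref = attr(fm, "knn_ref"),
                 sites = sites, n_features_encoded = ncol(fm),
                 config = config, config_hash = config_hash(config)),
            class = "acetyl_model")
}

#' @export
print.acetyl_model <- function(x, ...) {
  cat("Lysine acetylation site predictor (RBF-SVM)\n")
  cat("  sites: ", nrow(x$sites), " (",
      sum(x$sites$label == "positive"), " positive), window length ",
      2 * x$L + 1, "\n", sep = "")
  cat("  selected features: ", length(x$selection$features), " of ",
      x$n_features_encoded, " encoded (", length(x$selection$counts),
      " subtypes)\n", sep = "")
  cat("  cost = ", format(x$cost), ", gamma = ", format(x$gamma),
      ", config ", x$config_hash, "\n", sep = "")
  cat(sprintf("  cross-validated: ACC %.3f, MCC %.3f, AUC %.3f\n",
              x$cv$ACC, x$cv$MCC, x$cv$AUC))
  invisible(x)
}

#' @export
summary.acetyl_model <- function(object, ...) {
  structure(list(model = object), class = "summary.acetyl_model")
}

#' @export
print.summary.acetyl_model <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nSelected features per subtype:\n")
  print(m$selection$counts)
  cat("\nCross-validated performance (pooled out-of-fold):\n")
  perf <- unlist(m$cv[c("MCC", "ACC", "SEN", "SPE", "PRE", "AUC")])
  print(round(perf, 3))
  invisible(x)
}

#' Selected features and their label correlations
#'
#' @param object A fitted model.
#' @param ... Unused.
#' @return Named numeric vector: the Pearson correlation with the class
#'   label of every selected feature, in final feature order.
#' @export
coef.acetyl_model <- function(object, ...) {
  unlist(lapply(object$selection$per_subtype, function(r) {
    stats::setNames(r$pcc %||% rep(NA_real_, length(r$features)), r$features)
  }), use.names = TRUE)
}

#' ROC curve of the cross-validated model
#'
#' @param x A fitted model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.acetyl_model <- function(x, ...) {
  roc <- x$cv$roc
  graphics::plot(roc$fpr, roc$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("Cross-validated ROC (AUC = %.3f)", x$cv$AUC),
                 ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Predict acetylation for new lysine sites
#'
#' Encodes only the subtypes the model's selected features need (the
#' nearest-neighbour reference is the model's training reference, without
#' self-exclusion) and applies the fitted SVM.  A profile channel required
#' by the selected features but absent from `profiles` raises a
#' channel-missing error.
#'
#' @param object A fitted `"acetyl_model"`.
#' @param proteins Named list of protein records.
#' @param sites Site data frame (`protein_id`, `position`); labels are not
#'   required.
#' @param profiles Optional named list of residue profiles.
#' @param newdata Alternatively, an already-encoded feature matrix.
#' @param ... Unused.
#' @return A data frame with `protein_id`, `position`, `decision` (larger
#'   means more likely acetylated) and predicted `label`.
#' @export
predict.acetyl_model <- function(object, proteins = NULL, sites = NULL,
                                 profiles = NULL, newdata = NULL, ...) {
  if (is.null(newdata)) {
    stopifnot(!is.null(proteins), !is.null(sites))
    if (nrow(sites) == 0L) {
      return(data.frame(protein_id = character(0), position = integer(0),
                        decision = numeric(0), label = character(0),
                        stringsAsFactors = FALSE))
    }
    sites <- validate_sites(transform(sites, label = "unknown"), proteins)
    needed <- unique(sub("\\..*$", "", object$selection$features))
    newdata <- encode_features(proteins, sites, profiles = profiles,
                               L = object$L, subtypes = needed,
                               knn_ref = object$knn_ref,
                               knn_exclude_self = FALSE)
  }
  keys <- attr(newdata, "site_keys")
  pred <- predict(object$svm, unclass(newdata))
  data.frame(protein_id = keys$protein_id, position = keys$position,
             decision = pred$decision, label = pred$label,
             stringsAsFactors = FALSE)
}

#' Write predictions as TSV
#'
#' @param predictions Data frame from [predict.acetyl_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  out <- predictions
  out$decision <- format_full(out$decision)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save / load a fitted model
#'
#' The model artifact bundles the fitted SVM, scaling statistics, selected
#' feature names, nearest-neighbour reference and configuration hash;
#' reloading reproduces in-memory predictions exactly.
#'
#' @param model A fitted `"acetyl_model"`.
#' @param path File path.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "acetyl_model"))
  model
}
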