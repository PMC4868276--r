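# Per-subtype feature ranking and greedy stepwise selection.

#' Rank features by Pearson correlation with the class label
#'
#' Computes, per subtype present in the matrix, the Pearson correlation of
#' every feature with the 0/1 class vector and orders features by
#' descending absolute correlation (a strong negative correlate is as
#' informative as a positive one); ties are broken by feature name, then by
#' original column order.  Constant features receive a correlation of 0 and
#' sort last.
#'
#' @param fm A labelled feature matrix.
#' @return A named list of ranked lists, one per subtype, each a data frame
#'   with columns `feature` and `pcc`.
#' @export
rank_by_pcc <- function(fm) {
  labels <- attr(fm, "labels")
  if (is.null(labels) || length(unique(labels)) < 2L) {
    stop("ranking requires labels with both classes present")
  }
  y <- as.numeric(labels == "positive")
  pcc <- suppressWarnings(as.vector(stats::cor(unclass(fm), y)))
  pcc[is.na(pcc)] <- 0
  subtype <- attr(fm, "subtype")
  out <- list()
  for (st in SUBTYPES[SUBTYPES %in% unique(subtype)]) {
    idx <- which(subtype == st)
    ord <- idx[order(-abs(pcc[idx]), colnames(fm)[idx], idx)]
    out[[st]] <- data.frame(feature = colnames(fm)[ord], pcc = pcc[ord],
                            stringsAsFactors = FALSE)
  }
  out
}

#' Greedy stepwise selection along a ranked feature list
#'
#' Walks the ranked list once; a candidate joins the model iff the
#' cross-validated SVM accuracy of the incumbent set plus the candidate
#' *strictly* increases.  The first-ranked feature is accepted
#' unconditionally (the empty set has baseline accuracy 0), so at least one
#' feature is always selected and the accuracy trajectory is strictly
#' increasing by construction.  The same fold plan is reused for every
#' evaluation.
#'
#' @param fm A labelled feature matrix.
#' @param ranked Ranked list for one subtype (data frame from
#'   [rank_by_pcc()]).
#' @param fold Integer fold assignment per site.
#' @param cost,gamma SVM hyperparameters, held fixed during the pass.
#' @param max_evaluations Optional cap on the number of candidate
#'   evaluations (default unlimited), a runtime guard for wide subtypes.
#' @return A list with `features` (accepted names) and `trajectory`
#'   (cross-validated accuracy after each acceptance).
#' @export
stepwise_select <- function(fm, ranked, fold, cost = 1, gamma = NULL,
                            max_evaluations = Inf) {
  stopifnot(nrow(ranked) > 0L)
  labels <- attr(fm, "labels")
  x <- unclass(fm)
  if (is.null(gamma)) gamma <- 1 / nrow(ranked)
  accepted <- character(0)
  trajectory <- numeric(0)
  best <- 0
  n_eval <- 0L
  for (cand in ranked$feature) {
    if (n_eval >= max_evaluations) break
    n_eval <- n_eval + 1L
    acc <- cv_accuracy(x[, c(accepted, cand), drop = FALSE], labels, fold,
                       cost, gamma)
    if (acc > best || length(accepted) == 0L) {
      accepted <- c(accepted, cand)
      best <- max(acc, best)
      trajectory <- c(trajectory, best)
    }
  }
  list(features = accepted, trajectory = trajectory)
}

#' Combine per-subtype selections into the final feature set
#'
#' Concatenates the accepted per-subtype lists in the fixed subtype order
#' and records per-subtype counts; an empty subtype is omitted with a
#' warning.
#'
#' @param results Named list (by subtype) of [stepwise_select()] results.
#' @return An object of class `"selection_result"` with elements
#'   `features`, `per_subtype` (the input results), and `counts`.
#' @export
assemble_final_set <- function(results) {
  stopifnot(length(results) >= 1L)
  results <- results[SUBTYPES[SUBTYPES %in% names(results)]]
  empty <- vapply(results, function(r) length(r$features) == 0L, logical(1))
  if (any(empty)) {
    warning("subtype(s) with no accepted features omitted: ",
            paste(names(results)[empty], collapse = ", "))
    results <- results[!empty]
  }
  features <- unlist(lapply(results, `[[`, "features"), use.names = FALSE)
  counts <- vapply(results, function(r) length(r$features), integer(1))
  structure(list(features = features, per_subtype = results, counts = counts),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selected features:", length(x$features), "over",
      length(x$counts), "subtypes\n")
  print(x$counts)
  invisible(x)
}

# Full per-subtype selection driver: rank, tune (cost, gamma) once per
# subtype on the whole subtype block, then run the stepwise pass with the
# tuned parameters.  Returns the per-subtype results plus tuning metadata.
select_features <- function(fm, fold, grid = svm_grid(),
                            max_evaluations = Inf) {
  ranked <- rank_by_pcc(fm)
  subtype <- attr(fm, "subtype")
  labels <- attr(fm, "labels")
  results <- list()
  tuning <- list()
  for (st in names(ranked)) {
    x_st <- unclass(fm)[, subtype == st, drop = FALSE]
    gs <- grid_search(x_st, labels, grid = grid, fold = fold)
    sel <- stepwise_select(fm, ranked[[st]], fold, cost = gs$cost,
                           gamma = gs$gamma,
                           max_evaluations = max_evaluations)
    sel$pcc <- ranked[[st]]$pcc[match(sel$features, ranked[[st]]$feature)]
    results[[st]] <- sel
    tuning[[st]] <- list(cost = gs$cost, gamma = gs$gamma)
  }
  list(results = results, tuning = tuning, ranked = ranked)
}
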