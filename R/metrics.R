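# Binary-classification evaluation: confusion-based metrics and ROC/AUC.

#' Confusion counts from true and predicted labels
#'
#' @param truth,predicted Character vectors over
#'   `"positive"`/`"negative"`.
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  c(TP = sum(truth == "positive" & predicted == "positive"),
    TN = sum(truth == "negative" & predicted == "negative"),
    FP = sum(truth == "negative" & predicted == "positive"),
    FN = sum(truth == "positive" & predicted == "negative"))
}

#' Threshold-independent classification metrics from confusion counts
#'
#' Evaluates `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' `ACC = (TP+TN)/n`, `SEN = TP/(TP+FN)`, `SPE = TN/(TN+FP)` and
#' `PRE = TP/(TP+FP)`.  A zero factor in the MCC denominator yields
#' `MCC = 0`; an undefined precision (`TP+FP = 0`) yields 0 with a warning.
#'
#' @param counts Named vector with elements `TP`, `TN`, `FP`, `FN`.
#' @return Named numeric vector `c(MCC, ACC, SEN, SPE, PRE)`.
#' @export
compute_metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); tn <- as.numeric(counts[["TN"]])
  fp <- as.numeric(counts[["FP"]]); fn <- as.numeric(counts[["FN"]])
  n <- tp + tn + fp + fn
  stopifnot(n > 0)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  sen <- if (tp + fn > 0) tp / (tp + fn) else 0
  spe <- if (tn + fp > 0) tn / (tn + fp) else 0
  pre <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("precision undefined (no predicted positives); reported as 0")
    0
  }
  c(MCC = mcc, ACC = (tp + tn) / n, SEN = sen, SPE = spe, PRE = pre)
}

#' ROC curve and AUC from decision values
#'
#' Sweeps the unique decision values as thresholds (ties grouped, so tied
#' scores produce a diagonal ROC segment) and integrates the curve by the
#' trapezoidal rule.  The AUC equals the Mann-Whitney statistic: the
#' probability that a random positive outscores a random negative, counting
#' ties as one half.
#'
#' @param labels Character labels (`"positive"`/`"negative"`), both classes
#'   present.
#' @param scores Numeric decision values, larger meaning more positive.
#' @return A list with `auc` and `roc`, a data frame of (FPR, TPR) points
#'   starting at (0, 0) and ending at (1, 1).
#' @export
compute_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  np <- sum(labels == "positive")
  nn <- sum(labels == "negative")
  if (np == 0L || nn == 0L) {
    stop("ROC requires both classes to be present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- labels[ord] == "positive"
  # cumulative counts at each tie-group boundary
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, cumsum(pos)[last_of_group] / np)
  fpr <- c(0, cumsum(!pos)[last_of_group] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc, roc = data.frame(fpr = fpr, tpr = tpr))
}

#' Full evaluation report
#'
#' @param truth True labels.
#' @param predicted Predicted labels.
#' @param scores Decision values for the ROC.
#' @return A list with the five confusion metrics, `AUC`, the ROC points
#'   and the confusion counts.
#' @export
eval_report <- function(truth, predicted, scores) {
  counts <- confusion_counts(truth, predicted)
  roc <- compute_auc(truth, scores)
  c(as.list(compute_metrics(counts)),
    list(AUC = roc$auc, roc = roc$roc, counts = counts))
}
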