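# Evaluation metrics, ROC/AUC, grid search and the SVM wrapper.

test_that("confusion metrics evaluate the printed formulas exactly", {
  perfect <- compute_metrics(c(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(unname(perfect), c(1, 1, 1, 1, 1))

  chance <- compute_metrics(c(TP = 25, TN = 25, FP = 25, FN = 25))
  expect_equal(unname(chance[c("MCC", "ACC")]), c(0, 0.5))

  m <- compute_metrics(c(TP = 40, FN = 10, TN = 30, FP = 20))
  expect_equal(unname(m["SEN"]), 0.8)
  expect_equal(unname(m["SPE"]), 0.6)
  expect_equal(unname(m["PRE"]), 2 / 3)
  expect_equal(unname(m["ACC"]), 0.7)
  expect_equal(unname(m["MCC"]),
               (40 * 30 - 20 * 10) / sqrt((40 + 20) * (40 + 10) *
                                            (30 + 20) * (30 + 10)))

  # zero denominator conventions
  expect_warning(p0 <- compute_metrics(c(TP = 0, TN = 10, FP = 0, FN = 5)),
                 "precision undefined")
  expect_equal(unname(p0[c("MCC", "PRE")]), c(0, 0))
})

test_that("AUC equals Mann-Whitney pair counting and handles ties", {
  labels <- c(rep("positive", 3), rep("negative", 3))
  expect_equal(compute_auc(labels, c(3, 2.5, 2, 1, 0.5, 0))$auc, 1)
  expect_equal(compute_auc(labels, rep(0.7, 6))$auc, 0.5)
  expect_error(compute_auc(rep("positive", 4), 1:4), "both classes")

  mann_whitney <- function(labels, s) {
    pos <- s[labels == "positive"]; neg <- s[labels == "negative"]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(pairs)
  }
  set.seed(61)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    labels <- sample(c("positive", "negative"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("positive", "negative")
    s <- round(stats::rnorm(n), sample(0:2, 1))   # rounding forces ties
    r <- compute_auc(labels, s)
    expect_equal(r$auc, mann_whitney(labels, s))
    # complement and monotone-transform identities
    expect_equal(compute_auc(labels, -s)$auc, 1 - r$auc)
    expect_equal(compute_auc(labels, exp(s))$auc, r$auc)
    # ROC path: starts (0,0), ends (1,1), monotone in both coordinates
    expect_equal(unlist(r$roc[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$roc[nrow(r$roc), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(62)
  labels <- sample(c("positive", "negative"), 150, replace = TRUE)
  s <- stats::rnorm(150) + (labels == "positive")
  ours <- compute_auc(labels, s)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = s, levels = c("negative", "positive"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs)
})

test_that("grid search maximises CV accuracy with smallest-point ties", {
  set.seed(71)
  n <- 60L
  labels <- rep(c("positive", "negative"), each = n / 2)
  x <- cbind(f1 = as.numeric(labels == "positive") * 4 + stats::rnorm(n, sd = 0.2),
             f2 = stats::rnorm(n))
  fold <- acetylsite:::stratified_folds(labels, 5L, seed = 3L)
  gs <- grid_search(x, labels, svm_grid(cost = c(0.25, 1, 4),
                                        gamma = c(0.05, 0.25, 1)), fold)
  expect_equal(gs$accuracy, 1)

  # brute-force oracle over the same 3 x 3 lattice
  grid <- svm_grid(cost = c(0.25, 1, 4), gamma = c(0.05, 0.25, 1))
  acc <- vapply(seq_len(nrow(grid)), function(i)
    acetylsite:::cv_accuracy(x, labels, fold, grid$cost[i], grid$gamma[i]),
    numeric(1))
  expect_equal(gs$trace$accuracy, acc)
  best <- which(acc == max(acc))
  best <- best[order(grid$cost[best], grid$gamma[best])][1]
  expect_equal(c(gs$cost, gs$gamma), c(grid$cost[best], grid$gamma[best]))

  # symmetric noise ties resolve to the smallest lattice point
  x_noise <- matrix(rep(c(-1, 1), n / 2), n, 2)
  labels_sym <- rep(c("positive", "negative"), n / 2)
  fold_sym <- rep(1:5, length.out = n)
  gs_noise <- grid_search(x_noise, labels_sym,
                          svm_grid(cost = c(1, 2), gamma = c(0.5, 1)),
                          fold_sym)
  expect_equal(c(gs_noise$cost, gs_noise$gamma), c(1, 0.5))
})

test_that("SVM fitting scales, predicts and round-trips through disk", {
  set.seed(81)
  n <- 50L
  labels <- rep(c("positive", "negative"), each = n / 2)
  x <- cbind(a = as.numeric(labels == "positive") * 3 + stats::rnorm(n, sd = 0.1),
             b = stats::rnorm(n),
             const = rep(2, n))
  fit <- svm_fit(x, labels, cost = 4, gamma = 0.5)
  pred <- predict(fit, x)
  expect_equal(pred$label, labels)                 # separable training data
  expect_true(all(pred$decision[labels == "positive"] > 0))

  # constant training feature maps to 0 even for new values
  x_new <- x; x_new[, "const"] <- stats::rnorm(n)
  expect_equal(predict(fit, x_new), pred)

  # column permutation is irrelevant; missing columns are named
  expect_equal(predict(fit, x[, c("b", "const", "a")]), pred)
  expect_error(predict(fit, x[, c("a", "b")]), "const")

  tf <- withr::local_tempfile(fileext = ".rds")
  saveRDS(fit, tf)
  expect_equal(predict(readRDS(tf), x), pred)

  expect_error(svm_fit(x, rep("positive", n), 1, 1), "each class")
})

test_that("cross-validation never leaks validation scaling and reproduces", {
  set.seed(91)
  n <- 60L
  labels <- sample(rep(c("positive", "negative"), each = n / 2))
  x <- matrix(stats::rnorm(n * 3), n, 3,
              dimnames = list(NULL, c("u", "v", "w")))
  fold <- acetylsite:::stratified_folds(labels, 5L, seed = 13L)
  expect_identical(fold, acetylsite:::stratified_folds(labels, 5L, seed = 13L))
  expect_equal(sort(unique(fold)), 1:5)
  expect_true(all(abs(diff(table(fold, labels))) <= 1))

  a1 <- acetylsite:::cv_accuracy(x, labels, fold, 1, 0.3)
  a2 <- acetylsite:::cv_accuracy(x, labels, fold, 1, 0.3)
  expect_identical(a1, a2)

  oof <- acetylsite:::cv_predict(x, labels, fold, 1, 0.3)
  expect_length(oof$decision, n)
  expect_true(all(oof$label %in% c("positive", "negative")))
})
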