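# The fitted model object: pipeline behaviour, methods, reproducibility.

fit_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- small_synth()
      cache <<- acetyl_fit(d$proteins, d$sites,
                           subtypes = c("LC", "PWAA", "KNN"),
                           grid = svm_grid(cost = c(1, 8),
                                           gamma = c(0.05, 0.25)),
                           seed = 11L)
    }
    cache
  }
})

test_that("the fitted model carries selection, tuning and CV performance", {
  m <- fit_small()
  expect_s3_class(m, "acetyl_model")
  expect_true(all(names(m$selection$counts) %in% c("LC", "PWAA", "KNN")))
  expect_gte(length(m$selection$features), 1L)
  expect_identical(m$svm$features, m$selection$features)
  for (metric in c("MCC", "ACC", "SEN", "SPE", "PRE", "AUC")) {
    expect_true(is.numeric(m$cv[[metric]]))
  }
  expect_gte(m$cv$AUC, 0); expect_lte(m$cv$AUC, 1)
  # every subtype trajectory is strictly increasing
  for (r in m$selection$per_subtype) {
    expect_true(all(diff(r$trajectory) > 0))
  }
  expect_match(m$config_hash, "^[0-9a-f]{8}$")

  expect_output(print(m), "acetylation site predictor")
  expect_output(print(summary(m)), "Selected features per subtype")
  cf <- coef(m)
  expect_length(cf, length(m$selection$features))
  expect_true(all(abs(cf) <= 1))

  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(m))
})

test_that("prediction is deterministic, order-free and disk-stable", {
  m <- fit_small()
  d <- small_synth()
  pred <- predict(m, d$proteins, d$sites)
  expect_named(pred, c("protein_id", "position", "decision", "label"))
  expect_equal(nrow(pred), nrow(d$sites))
  expect_identical(pred, predict(m, d$proteins, d$sites))
  expect_true(all((pred$decision > 0) == (pred$label == "positive")))

  # training predictions beat chance on the planted signal
  acc <- mean(pred$label == d$sites$label)
  expect_gt(acc, 0.5)

  # feature matrix route with permuted columns gives identical results
  fm <- encode_features(d$proteins, d$sites, subtypes = c("LC", "PWAA", "KNN"),
                        knn_ref = m$knn_ref, knn_exclude_self = FALSE)
  perm <- fm[, sample(ncol(fm)), drop = FALSE]
  attr(perm, "site_keys") <- attr(fm, "site_keys")
  expect_equal(predict(m, newdata = perm), pred)

  # empty site list -> empty prediction table
  empty <- predict(m, d$proteins, d$sites[0, ])
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("protein_id", "position", "decision", "label"))

  # save -> load -> predict reproduces in-memory predictions
  tf <- withr::local_tempfile(fileext = ".rds")
  save_model(m, tf)
  expect_equal(predict(load_model(tf), d$proteins, d$sites), pred)

  # a required channel missing at prediction time names the problem
  dp <- generate_dataset(synthetic_spec(n_proteins = 6L, seed = 2L))
  mp <- acetyl_fit(dp$proteins, dp$sites, profiles = dp$profiles,
                   subtypes = c("LC", "HSE"),
                   grid = svm_grid(cost = 1, gamma = 0.1), seed = 1L)
  stripped <- lapply(dp$profiles, function(pr) { pr$hse <- NULL; pr })
  expect_error(predict(mp, dp$proteins, dp$sites, profiles = stripped),
               "channel missing")
})

test_that("refitting with an identical configuration reproduces everything", {
  d <- small_synth()
  args <- list(d$proteins, d$sites, subtypes = c("LC", "PWAA", "KNN"),
               grid = svm_grid(cost = c(1, 8), gamma = c(0.05, 0.25)),
               seed = 11L)
  m1 <- do.call(acetyl_fit, args)
  m2 <- do.call(acetyl_fit, args)
  expect_identical(m1$config_hash, m2$config_hash)
  expect_identical(m1$selection$features, m2$selection$features)
  expect_identical(m1$selection$per_subtype, m2$selection$per_subtype)
  expect_identical(c(m1$cost, m1$gamma), c(m2$cost, m2$gamma))
  expect_identical(m1$cv$AUC, m2$cv$AUC)
  expect_identical(predict(m1, d$proteins, d$sites),
                   predict(m2, d$proteins, d$sites))
})

test_that("the command-line surface ties the pipeline together", {
  root <- withr::local_tempdir()
  data_dir <- file.path(root, "data")
  expect_message(cli_main(c("synth", "--out", data_dir, "--n", "12",
                            "--seed", "4")),
                 "wrote synthetic dataset")

  fm_path <- file.path(root, "features.tsv")
  expect_message(cli_main(c("encode", "--fasta",
                            file.path(data_dir, "proteins.fasta"),
                            "--sites", file.path(data_dir, "sites.tsv"),
                            "--out", fm_path,
                            "--subtypes", "LC,PWAA")),
                 "23 features")
  fm <- read_feature_matrix(fm_path)
  expect_equal(ncol(fm), 23L)

  model_path <- file.path(root, "model.rds")
  report_path <- file.path(root, "report.json")
  out <- capture.output(cli_main(c("select-train",
    "--fasta", file.path(data_dir, "proteins.fasta"),
    "--sites", file.path(data_dir, "sites.tsv"),
    "--model", model_path, "--subtypes", "LC,PWAA,KNN",
    "--seed", "4", "--report", report_path)))
  expect_true(file.exists(model_path))
  report <- jsonlite::read_json(report_path)
  expect_true(all(c("MCC", "ACC", "SEN", "SPE", "PRE", "AUC") %in%
                    names(report$metrics)))

  pred_path <- file.path(root, "pred.tsv")
  expect_message(cli_main(c("predict", "--model", model_path,
                            "--fasta", file.path(data_dir, "proteins.fasta"),
                            "--sites", file.path(data_dir, "sites.tsv"),
                            "--out", pred_path)),
                 "predictions")
  pred <- utils::read.delim(pred_path)
  expect_equal(nrow(pred), 24L)

  metrics_path <- file.path(root, "metrics.json")
  expect_message(cli_main(c("evaluate", "--predictions", pred_path,
                            "--sites", file.path(data_dir, "sites.tsv"),
                            "--out", metrics_path)),
                 "metrics")
  metrics <- jsonlite::read_json(metrics_path)
  expect_true(metrics$ACC >= 0 && metrics$ACC <= 1)

  # window-size sweep: per-position blocks scale with the window length
  for (ws in c(11L, 13L)) {
    sweep_path <- file.path(root, paste0("sweep", ws, ".tsv"))
    suppressMessages(cli_main(c("encode",
      "--fasta", file.path(data_dir, "proteins.fasta"),
      "--sites", file.path(data_dir, "sites.tsv"),
      "--out", sweep_path, "--subtypes", "AAindex",
      "--window", as.character((ws - 1L) %/% 2L))))
    expect_equal(ncol(read_feature_matrix(sweep_path)), 10L + 5L * ws)
  }

  expect_error(cli_main(c("nonsense")), "unknown command")
  expect_error(cli_main(c("encode", "--fasta")), "malformed|missing")
})
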