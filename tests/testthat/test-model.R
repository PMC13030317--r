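test_that("built models emit normalized probabilities, seeded identically", {
  cfg <- test_model_config(seed = 3)
  m1 <- build_model(cfg, 50)
  m2 <- build_model(cfg, 50)
  expect_identical(m1$layers, m2$layers)
  expect_gt(m1$n_params, 0)

  set.seed(1)
  x <- array(rnorm(5 * 50 * 7), c(5, 50, 7))
  p <- predict(m1, x, type = "prob")
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)

  # window length incompatible with pooling depth
  expect_error(build_model(cfg, 2), "pooling")
  # wrong window shape at prediction time
  expect_error(predict(m1, array(0, c(2, 49, 7))), "49")
})

test_that("TCN receptive field follows the closed form", {
  cfg <- test_model_config()
  expect_equal(receptive_field(cfg), 1 + 2 * (3 - 1) * (1 + 2 + 4))
  cfg2 <- expression_model(tcn = list(filters = 8, kernel = 5,
                                      dilations = c(1, 2, 4, 8),
                                      dropout = 0))
  expect_equal(receptive_field(cfg2), 1 + 2 * 4 * 15)
  expect_error(expression_model(tcn = list(filters = 8, kernel = 3,
                                           dilations = c(1, 3),
                                           dropout = 0)),
               "powers of 2")
})

test_that("argmax labels use the documented tie-break order", {
  cfg <- test_model_config()
  m <- build_model(cfg, 8)
  probs <- rbind(c(0.7, 0.1, 0.1, 0.1), rep(0.25, 4), c(0.1, 0.1, 0.4, 0.4))
  lab <- expression_levels()[max.col(probs, ties.method = "first")]
  expect_equal(lab, c("neutral", "neutral", "frown"))
})

test_that("training learns separable synthetic windows and early-stops", {
  co <- generate_cohort(test_synth_config(n = 3, seed = 19, snr = 40))
  wins <- calibration_windows(co)
  st <- femgxdyn:::stack_windows(wins)
  val <- st$participant == "P03"
  cfg <- test_model_config(seed = 5)
  m <- build_model(cfg, st$w)
  m <- train_model(m, st$x[!val, , , drop = FALSE], st$y[!val],
                   st$x[val, , , drop = FALSE], st$y[val])
  expect_true(m$trained)
  expect_lte(nrow(m$history), cfg$optimizer$max_epochs)
  pred_tr <- predict(m, st$x[!val, , , drop = FALSE])
  expect_gte(mean(pred_tr == st$y[!val]), 0.99)
  # held-out windows from the validation participant classify correctly
  pred_va <- predict(m, st$x[val, , , drop = FALSE])
  expect_gte(suppressWarnings(
    evaluate_classification(st$y[val], pred_va))$macro_f1, 0.9)

  expect_error(train_model(m, st$x[0, , , drop = FALSE], character(0)),
               "at least 2 classes|empty")
})

test_that("trained models serialize without changing predictions", {
  co <- generate_cohort(test_synth_config(n = 3, seed = 23, snr = 40,
                                          scene_duration = 20,
                                          baseline_duration = 20))
  wins <- calibration_windows(co)
  st <- femgxdyn:::stack_windows(wins)
  cfg <- test_model_config(seed = 5)
  cfg$optimizer$max_epochs <- 3
  m <- build_model(cfg, st$w)
  m <- train_model(m, st$x, st$y)
  f <- withr::local_tempfile(fileext = ".rds")
  saveRDS(m, f)
  m2 <- readRDS(f)
  expect_identical(predict(m, st$x, type = "prob"),
                   predict(m2, st$x, type = "prob"))
})

test_that("LOPO folds are participant-disjoint and complete", {
  co <- generate_cohort(test_synth_config(n = 4, seed = 29, snr = 40,
                                          scene_duration = 20,
                                          baseline_duration = 20))
  wins <- calibration_windows(co)
  cfg <- test_model_config(seed = 7)
  cfg$optimizer$max_epochs <- 4
  res <- lopo_cross_validate(wins, cfg)
  expect_length(res$folds, 4)
  expect_setequal(vapply(res$folds, function(f) f$test_participant,
                         character(1)), sprintf("P%02d", 1:4))
  for (f in res$folds) {
    expect_length(intersect(f$train_participants, f$val_participants), 0)
    expect_false(f$test_participant %in%
                   c(f$train_participants, f$val_participants))
  }
  expect_equal(nrow(res$aggregate$test), 8)

  expect_error(lopo_cross_validate(wins[vapply(wins, function(z)
    z$participant, character(1)) %in% c("P01", "P02")], cfg),
    ">= 3 participants")
})

test_that("retraining on the full set warns about missing participants", {
  co <- generate_cohort(test_synth_config(n = 3, seed = 31, snr = 40,
                                          scene_duration = 20,
                                          baseline_duration = 20))
  wins <- calibration_windows(co)
  cfg <- test_model_config(seed = 7)
  cfg$optimizer$max_epochs <- 4
  expect_warning(retrain_full(wins, cfg,
                              expected_participants = sprintf("P%02d", 1:4)),
                 "P04")
  m <- retrain_full(wins, cfg)
  expect_true(m$trained)
  expect_s3_class(m$holdout_metrics, "femg_metrics")
})

test_that("all baseline architectures train and beat chance at high SNR", {
  co <- generate_cohort(test_synth_config(n = 3, seed = 37, snr = 40,
                                          scene_duration = 20,
                                          baseline_duration = 20,
                                          calibration_hold = 3))
  wins <- calibration_windows(co)
  cfg <- test_model_config(seed = 9)
  cfg$optimizer$max_epochs <- 30
  cfg$optimizer$patience <- 8
  cfg$optimizer$lr <- 2e-3
  cfg$cnn$filters <- c(8, 16)
  cfg$tcn$filters <- 16
  cfg$fc$hidden <- 16
  cfg$rnn$hidden <- 12
  for (arch in c("cnn", "tcn", "lstm", "cnn-lstm", "gru", "cnn-tcn")) {
    res <- train_baseline(arch, wins, cfg, val_participants = 1)
    mf1 <- res$aggregate$test[res$aggregate$test$metric == "macro_f1",
                              "mean"]
    expect_gt(mf1, 0.25)
    # identical data/seed reproduce the result exactly
    if (arch == "gru") {
      res2 <- train_baseline(arch, wins, cfg, val_participants = 1)
      expect_equal(res$aggregate$test, res2$aggregate$test)
    }
  }
  expect_error(train_baseline("transformer", wins, cfg), "arg")
})
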