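# Cross-validation machinery, metrics, and training behaviour.

test_that("k-fold partitions are disjoint and covering", {
  for (np in list(c(100, 10), c(37, 5), c(10, 10), c(23, 2))) {
    folds <- kfold_indices(np[1], np[2], seed = 3)
    tests <- lapply(folds, `[[`, "test")
    expect_equal(sort(unlist(tests)), seq_len(np[1]))
    expect_equal(sum(duplicated(unlist(tests))), 0)
    for (f in folds) {
      expect_setequal(c(f$train, f$test), seq_len(np[1]))
      expect_length(intersect(f$train, f$test), 0)
    }
  }
  expect_error(kfold_indices(5, 10), "exceed")
  expect_error(kfold_indices(5, 1), "at least 2")
})

test_that("stratified folds preserve class ratios to within one sample", {
  labels <- rep(c(1, 0), c(60, 40))
  folds <- kfold_indices(100, 10, labels = labels, seed = 5)
  for (f in folds) {
    expect_equal(sum(labels[f$test] == 1), 6)
    expect_equal(sum(labels[f$test] == 0), 4)
  }
  # determinism
  f2 <- kfold_indices(100, 10, labels = labels, seed = 5)
  expect_identical(folds, f2)
  f3 <- kfold_indices(100, 10, labels = labels, seed = 6)
  expect_false(identical(folds, f3))
})

test_that("grouped folds keep whole groups together", {
  groups <- rep(letters[1:10], each = 8)
  folds <- kfold_indices(80, 5, groups = groups, seed = 2)
  for (f in folds) {
    expect_length(intersect(unique(groups[f$test]),
                            unique(groups[f$train])), 0)
  }
})

test_that("binary metrics: degenerate, chance and hand-computed cases", {
  # perfect predictions
  m <- binary_metrics(c(0, 1, 0, 1), c(0, 1, 0, 1), c(0.1, 0.9, 0.2, 0.8))
  expect_equal(unlist(m), c(accuracy = 1, precision = 1, f1 = 1, auc = 1))
  # constant predictor on a balanced fold: chance accuracy and AUC
  truth <- rep(c(0, 1), 5)
  m2 <- binary_metrics(truth, rep(1, 10), rep(0.7, 10))
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$auc, 0.5)
  # printed 2x2 confusion: TP=3, FP=1, FN=1, TN=5
  truth3 <- c(rep(1, 3), rep(0, 1), rep(1, 1), rep(0, 5))
  pred3 <- c(rep(1, 3), rep(1, 1), rep(0, 1), rep(0, 5))
  m3 <- binary_metrics(truth3, pred3, pred3)
  expect_equal(m3$precision, 0.75)
  expect_equal(m3$f1, 0.75)
  # one-class fold: AUC missing with a warning
  expect_warning(m4 <- binary_metrics(rep(1, 4), rep(1, 4), runif(4)),
                 "single class")
  expect_true(is.na(m4$auc))
})

test_that("rank-based AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  truth <- rbinom(60, 1, 0.5)
  score <- runif(60) + truth * 0.3
  ref <- as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE)))
  expect_equal(auc_rank(score, truth), ref, tolerance = 1e-12)
})

test_that("training config and input validation", {
  expect_error(train_config(epochs = 0), "epochs")
  cfg <- train_config("valence", epochs = 2, seed = 1)
  sep <- separable_features(10)
  expect_error(train_model(model_spec(32), sep$X, rep(1L, 20), cfg),
               "both classes")
})

test_that("training learns a separable problem with decreasing loss", {
  sep <- separable_features(40)
  cfg <- train_config("valence", epochs = 25, seed = 9)
  fit <- train_model(model_spec(32, variant = "CNN"), sep$X, sep$y, cfg)
  expect_gte(max(fit$history$accuracy), 0.99)
  # 10-epoch moving average of the loss is non-increasing
  ma <- stats::filter(fit$history$loss, rep(1 / 10, 10), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_true(all(diff(ma) <= 1e-6))
  # training accuracy at convergence carries to held-out data
  hold <- separable_features(40, seed = 99)
  expect_gte(evaluate_model(fit, hold$X, hold$y)$accuracy, 0.95)
})

test_that("training is deterministic given the seed", {
  sep <- separable_features(15)
  cfg <- train_config("valence", epochs = 3, seed = 21)
  f1 <- train_model(model_spec(32, variant = "CNN"), sep$X, sep$y, cfg)
  f2 <- train_model(model_spec(32, variant = "CNN"), sep$X, sep$y, cfg)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$history, f2$history)
})

test_that("cross-validation aggregates folds with mean <= max", {
  sep <- separable_features(30)
  # small batches so batch-norm running statistics settle within few epochs
  cfg <- train_config("valence", epochs = 20, batch_size = 16, seed = 13)
  cv <- cross_validate(model_spec(32, variant = "CNN"), sep$X, sep$y, cfg,
                       k = 5)
  expect_equal(nrow(cv$folds), 5)
  expect_true(all(cv$mean <= cv$max + 1e-12))
  expect_gte(cv$mean["accuracy"], 0.9)
})

test_that("suite runners produce the expected experimental grids", {
  # combinatorics of the band suite: 4 singletons + 6 pairs + 4 triples
  subs <- band_subsets()
  expect_length(subs, 14)
  expect_equal(sum(lengths(subs) == 1), 4)
  expect_equal(sum(lengths(subs) == 2), 6)
  expect_equal(sum(lengths(subs) == 3), 4)
  # a tiny ablation grid has one row per variant per task
  feats <- fixture_features()
  cfg <- train_config(epochs = 2, seed = 3)
  res <- run_ablation_suite(feats[c(1:30, 101:130), ], cfg,
                            variants = c("CNN"), tasks = c("valence"), k = 2)
  expect_equal(nrow(res), 1)
  expect_named(res, c("variant", "task", "accuracy", "precision", "f1",
                      "auc", "max_accuracy"))
})

test_that("a band subset too short for the conv stack names the subset", {
  tiny <- de_matrix(matrix(rnorm(40), 20, 2),
                    band_names = c("theta", "alpha"),
                    channel_labels = "ch001",
                    row_meta = data.frame(valence = rep(0:1, 10),
                                          arousal = rep(0:1, 10)))
  cfg <- train_config(epochs = 1, seed = 1)
  expect_error(run_band_suite(tiny, cfg, subsets = list("theta"),
                              tasks = "valence", k = 2),
               "theta")
})
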