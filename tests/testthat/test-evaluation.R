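test_that("stratified splits have exact sizes and balanced classes", {
  set.seed(2)
  labels <- rep(0:3, times = c(80, 50, 40, 30))
  folds <- make_folds(labels, n_folds = 4, test_fraction = 0.3, base_seed = 42)
  expect_length(folds, 4)
  for (f in folds) {
    expect_length(f$test, round(0.3 * 200))
    expect_length(intersect(f$train, f$test), 0)
    expect_equal(sort(c(f$train, f$test)), 1:200)
    for (c in 0:3) {
      target <- 0.3 * sum(labels == c)
      expect_lte(abs(sum(labels[f$test] == c) - target), 1)
    }
  }
  # independent splits, reproducible per base seed
  f42 <- make_folds(labels, 3, 0.3, 42)
  f42b <- make_folds(labels, 3, 0.3, 42)
  f20 <- make_folds(labels, 3, 0.3, 20)
  expect_identical(f42, f42b)
  expect_false(identical(f42[[1]]$test, f20[[1]]$test))
  expect_false(identical(f42[[1]]$test, f42[[2]]$test))

  expect_error(make_folds(c(0, 0, 1), 2, 0.3, 1), "at least 2 samples")
  expect_error(make_folds(rep(0, 10), 2, 0.3, 1), "2 classes")
})

test_that("confusion metrics match hand-computed and brute-force values", {
  cm <- confusion_matrix(c(0L, 0L, 1L, 1L), c(0L, 1L, 1L, 1L), 2L)
  expect_equal(sum(cm), 4)
  m <- metrics_from_confusion(cm)
  expect_equal(m$accuracy, 75)
  expect_equal(m$precision, 100 * (1 + 2 / 3) / 2, tolerance = 1e-12)  # 83.33
  expect_equal(m$recall, 75)
  expect_equal(m$fscore, 100 * (2 / 3 + 0.8) / 2, tolerance = 1e-12)   # 73.33

  # perfect prediction
  diag <- confusion_matrix(rep(0:2, 5), rep(0:2, 5), 3L)
  md <- metrics_from_confusion(diag)
  expect_equal(c(md$accuracy, md$precision, md$recall, md$fscore),
               rep(100, 4))

  # published fold-1 count: 5823 correct of 6225
  expect_equal(round(100 * 5823 / 6225, 2), 93.54)

  set.seed(14)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    n <- sample(20:200, 1)
    true <- sample(0:(k - 1), n, replace = TRUE)
    pred <- sample(0:(k - 1), n, replace = TRUE)
    cm <- confusion_matrix(true, pred, k)
    got <- metrics_from_confusion(cm)
    want <- brute_metrics(true, pred, k)
    expect_equal(got$accuracy, want$accuracy, tolerance = 1e-12)
    expect_equal(got$precision, want$precision, tolerance = 1e-12)
    expect_equal(got$recall, want$recall, tolerance = 1e-12)
    expect_equal(got$fscore, want$fscore, tolerance = 1e-12)
    # marginalisation identities
    pc <- got$per_class
    expect_equal(pc$tp + pc$fn, unname(rowSums(cm)))
    expect_equal(sum(pc$tp), sum(diag(cm)))
  }
})

test_that("one-vs-rest AUC matches the pairwise-comparison oracle", {
  # perfectly ordered scores
  true <- rep(0:2, each = 4)
  scores <- matrix(0.01, 12, 3)
  scores[cbind(1:12, true + 1)] <- 0.98
  scores <- scores / rowSums(scores)
  expect_equal(ovr_auc(true, scores), 1)

  # label-independent scores sit near 1/2
  set.seed(31)
  n <- 2000
  true <- sample(0:2, n, replace = TRUE)
  raw <- matrix(runif(3 * n), n, 3)
  scores <- raw / rowSums(raw)
  expect_lt(abs(ovr_auc(true, scores) - 0.5), 0.03)

  # O(n^2) brute-force agreement, including midrank tie handling
  set.seed(32)
  true <- sample(0:2, 200, replace = TRUE)
  raw <- matrix(sample(seq(0.1, 1, 0.1), 600, replace = TRUE), 200, 3)
  scores <- raw / rowSums(raw)
  expect_equal(ovr_auc(true, scores), brute_ovr_auc(true, scores),
               tolerance = 1e-9)

  expect_warning(ovr_auc(c(0L, 0L, 0L, 1L, 1L), matrix(1 / 3, 5, 3)), "absent")
})

test_that("cross-validation reports per-fold metrics and ddof-1 summaries", {
  tbl <- make_benchmark_features(300, 12, k_informative = 6,
                                 class_separation = 2, n_classes = 3, seed = 12)
  fc <- structure(list(features = 0:11, n_estimators = 60L, learning_rate = 0.2,
                       max_depth = 3L, min_child_weight = 1L),
                  class = "final_config")
  cfg <- run_config(base_seed = 9, n_folds = 5L)
  cv <- cross_validate(fc, tbl, cfg)
  expect_equal(nrow(cv$folds), 5)
  expect_true(all(cv$folds$test_accuracy >= 0 & cv$folds$test_accuracy <= 100))
  expect_true(all(cv$folds$auc >= 0 & cv$folds$auc <= 1))
  expect_true(all(cv$folds$train_time >= 0))
  acc_row <- cv$summary[cv$summary$metric == "test_accuracy", ]
  expect_equal(acc_row$mean, mean(cv$folds$test_accuracy))
  expect_equal(acc_row$sd, sd(cv$folds$test_accuracy))  # sample sd, ddof = 1

  # metrics are reproducible (timings are not compared)
  cv2 <- cross_validate(fc, tbl, cfg)
  keep <- setdiff(colnames(cv$folds), c("train_time", "test_time"))
  expect_equal(cv$folds[, keep], cv2$folds[, keep])
})

test_that("seed sweeps are stable on separable synthetic data", {
  tbl <- make_benchmark_features(1800, 12, k_informative = 6,
                                 class_separation = 2.5, n_classes = 3, seed = 13)
  fc <- structure(list(features = sort(tbl$informative), n_estimators = 60L,
                       learning_rate = 0.2, max_depth = 3L,
                       min_child_weight = 1L),
                  class = "final_config")
  cfg <- run_config(n_folds = 5L)
  seeds <- seq(5L, 50L, by = 5L)
  sweep <- seed_sweep(fc, tbl, cfg, seeds)
  expect_equal(nrow(sweep), 10)
  expect_equal(sweep$seed, seeds)
  # the external-seed spread of mean accuracy stays under 2 points
  expect_lt(max(sweep$test_accuracy) - min(sweep$test_accuracy), 2)
  sweep2 <- seed_sweep(fc, tbl, cfg, seeds)
  expect_equal(sweep$test_accuracy, sweep2$test_accuracy)
})
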