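# Evaluation protocol: repeated stratified 70/30 splits, one-vs-rest
# confusion-matrix metrics with macro averaging, one-vs-rest AUC, across-fold
# means and sample (ddof = 1) standard deviations, wall-clock timing, and an
# external random-seed sweep.

# Largest-remainder stratified allocation: per-class test quotas sum exactly
# to round(test_fraction * n) while staying within one sample of the
# proportional target.
stratified_split <- function(labels, test_fraction, seed) {
  n <- length(labels)
  classes <- sort(unique(labels))
  counts <- vapply(classes, function(c) sum(labels == c), integer(1))
  if (any(counts < 2L)) {
    stop("every class needs at least 2 samples for a stratified split")
  }
  total_test <- round(test_fraction * n)
  raw <- test_fraction * counts
  quota <- floor(raw)
  quota <- pmin(pmax(quota, 1L), counts - 1L)  # keep every class on both sides
  short <- total_test - sum(quota)
  if (short > 0) {
    ord <- order(raw - floor(raw), decreasing = TRUE)
    for (k in ord) {
      if (short == 0) break
      if (quota[k] < counts[k] - 1L) {
        quota[k] <- quota[k] + 1L
        short <- short - 1L
      }
    }
  } else if (short < 0) {
    ord <- order(raw - floor(raw))
    for (k in ord) {
      if (short == 0) break
      if (quota[k] > 1L) {
        quota[k] <- quota[k] - 1L
        short <- short + 1L
      }
    }
  }
  with_seed(seed, {
    test <- unlist(lapply(seq_along(classes), function(k) {
      idx <- which(labels == classes[k])
      sample(idx, quota[k])
    }))
  })
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Build independent stratified train/test splits
#'
#' Each of the `n_folds` splits is an independent stratified random
#' subsampling split (not a partition): `round(test_fraction * n)` test
#' samples with per-class proportions within one sample of the stratified
#' target. Split i is seeded by `derive_seed(base_seed, i)`, so folds are
#' individually reproducible.
#'
#' @param labels integer class labels.
#' @param n_folds number of splits (default 10).
#' @param test_fraction held-out fraction (default 0.30).
#' @param base_seed master seed (default 42).
#' @return list of `n_folds` lists with integer `train` and `test` indices.
#' @export
make_folds <- function(labels, n_folds = 10L, test_fraction = 0.30,
                       base_seed = 42L) {
  stopifnot(n_folds >= 1, test_fraction > 0, test_fraction < 1)
  if (length(unique(labels)) < 2L) stop("need at least 2 classes")
  lapply(seq_len(n_folds), function(i) {
    stratified_split(labels, test_fraction, derive_seed(base_seed, i))
  })
}

#' Multiclass confusion matrix (rows = actual, columns = predicted)
#'
#' @param true,pred integer class labels (0-based).
#' @param n_classes number of classes; defaults to the largest label + 1.
#' @return `n_classes x n_classes` integer matrix.
#' @export
confusion_matrix <- function(true, pred, n_classes = max(c(true, pred)) + 1L) {
  stopifnot(length(true) == length(pred))
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(true)) {
    cm[true[i] + 1L, pred[i] + 1L] <- cm[true[i] + 1L, pred[i] + 1L] + 1L
  }
  dimnames(cm) <- list(actual = 0:(n_classes - 1L), predicted = 0:(n_classes - 1L))
  cm
}

#' Accuracy and macro precision/recall/F-score from a confusion matrix
#'
#' Per-class TP/FP/FN/TN are obtained by one-vs-rest marginalisation;
#' per-class precision, recall and F-score use the usual ratios with the
#' 0-when-denominator-0 convention, and macro values are their unweighted
#' means (macro F is the mean of per-class F, not the harmonic mean of macro
#' precision and recall). Accuracy is `trace/total`. All headline values are
#' percentages in [0, 100].
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @return list with `accuracy`, `precision`, `recall`, `fscore` (percent)
#'   and a `per_class` data frame (proportions in [0, 1]).
#' @export
metrics_from_confusion <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  fscore <- safe_div(2 * precision * recall, precision + recall)
  list(
    accuracy = 100 * sum(tp) / total,
    precision = 100 * mean(precision),
    recall = 100 * mean(recall),
    fscore = 100 * mean(fscore),
    per_class = data.frame(
      class = as.integer(rownames(cm)),
      tp = tp, fp = fp, fn = fn, tn = tn,
      precision = precision, recall = recall, fscore = fscore,
      row.names = NULL
    )
  )
}

#' Macro F1 of predictions (convenience wrapper)
#'
#' @inheritParams confusion_matrix
#' @return macro F1 as a proportion in [0, 1].
#' @export
macro_f1 <- function(true, pred, n_classes = max(c(true, pred)) + 1L) {
  metrics_from_confusion(confusion_matrix(true, pred, n_classes))$fscore / 100
}

#' Macro one-vs-rest AUC via the rank statistic
#'
#' For each class present in `true`, the one-vs-rest AUC is computed from the
#' midrank Mann-Whitney statistic of that class's score column; the result is
#' the unweighted mean over classes. Classes absent from `true` are skipped
#' with a warning.
#'
#' @param true integer labels (0-based).
#' @param scores numeric matrix, one column per class, rows summing to 1.
#' @return AUC in [0, 1].
#' @export
ovr_auc <- function(true, scores) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == length(true))
  n_classes <- ncol(scores)
  aucs <- rep(NA_real_, n_classes)
  for (c in seq_len(n_classes) - 1L) {
    pos <- true == c
    np <- sum(pos)
    nn <- sum(!pos)
    if (np == 0L || nn == 0L) {
      warning("class ", c, " absent from one side of the test set; skipped")
      next
    }
    r <- rank(scores[, c + 1L])  # midranks handle ties
    aucs[c + 1L] <- (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
  }
  mean(aucs, na.rm = TRUE)
}

#' Cross-validate a finalized configuration
#'
#' For each stratified 70/30 split: fit the XGBoost adapter on the training
#' partition using the consensus features and hyperparameters, then record
#' train and test accuracy/F-score/precision/recall (macro, percent), test
#' one-vs-rest AUC, and wall-clock train/test seconds. The summary reports
#' the across-fold mean and sample (ddof = 1) standard deviation of each test
#' metric. Conventional reporting rounds percentages to 2 decimals and AUC to
#' 5; the returned values are unrounded.
#'
#' @param final_config a `final_config` (see [finalize_config()]), or any
#'   list with `features` (0-based serials), `n_estimators`, `learning_rate`,
#'   `max_depth`, `min_child_weight`.
#' @param table a [feature_table()].
#' @param config a [run_config()] (uses `n_folds`, `test_fraction`,
#'   `base_seed`).
#' @return list with `folds` (data frame, one row per fold) and `summary`
#'   (data frame of mean and sd per metric).
#' @export
cross_validate <- function(final_config, table, config = run_config()) {
  values <- feature_values(table)
  labels <- feature_labels(table)
  n_classes <- max(labels) + 1L
  cols <- final_config$features + 1L
  stopifnot(all(cols >= 1L), all(cols <= ncol(values)))
  folds <- make_folds(labels, config$n_folds, config$test_fraction,
                      config$base_seed)
  rows <- lapply(seq_along(folds), function(i) {
    fold <- folds[[i]]
    adapter <- xgb_adapter(final_config$n_estimators, final_config$learning_rate,
                           final_config$max_depth, final_config$min_child_weight)
    tr_time <- system.time(
      model <- adapter_fit(adapter, values[fold$train, cols, drop = FALSE],
                           labels[fold$train], n_classes)
    )[["elapsed"]]
    tr_metrics <- metrics_from_confusion(confusion_matrix(
      labels[fold$train],
      adapter_predict(model, values[fold$train, cols, drop = FALSE]),
      n_classes))
    ts_time <- system.time(
      scores <- adapter_scores(model, values[fold$test, cols, drop = FALSE])
    )[["elapsed"]]
    pred <- max.col(scores) - 1L
    ts_metrics <- metrics_from_confusion(confusion_matrix(
      labels[fold$test], pred, n_classes))
    data.frame(
      fold = i,
      train_accuracy = tr_metrics$accuracy, train_fscore = tr_metrics$fscore,
      train_precision = tr_metrics$precision, train_recall = tr_metrics$recall,
      test_accuracy = ts_metrics$accuracy, test_fscore = ts_metrics$fscore,
      test_precision = ts_metrics$precision, test_recall = ts_metrics$recall,
      auc = ovr_auc(labels[fold$test], scores),
      train_time = tr_time, test_time = ts_time
    )
  })
  folds_df <- do.call(rbind, rows)
  metric_cols <- setdiff(colnames(folds_df), "fold")
  summary_df <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(folds_df[[m]]), numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(folds_df[[m]]), numeric(1)),
    row.names = NULL
  )
  list(folds = folds_df, summary = summary_df)
}

#' Repeat cross-validation under a sweep of external random seeds
#'
#' @inheritParams cross_validate
#' @param seeds integer vector of external seeds replacing `base_seed`.
#' @return data frame with one row per seed: seed, mean test metrics and mean
#'   AUC.
#' @export
seed_sweep <- function(final_config, table, config = run_config(),
                       seeds = config$external_seeds) {
  stopifnot(length(seeds) >= 1)
  rows <- lapply(seeds, function(s) {
    cfg <- config
    cfg$base_seed <- as.integer(s)
    cv <- cross_validate(final_config, table, cfg)
    means <- stats::setNames(cv$summary$mean, cv$summary$metric)
    data.frame(
      seed = s,
      test_accuracy = means[["test_accuracy"]],
      test_fscore = means[["test_fscore"]],
      test_precision = means[["test_precision"]],
      test_recall = means[["test_recall"]],
      auc = means[["auc"]]
    )
  })
  do.call(rbind, rows)
}
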