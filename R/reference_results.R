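# Published reference results for the KU-HAR study, shipped as plain-text
# data so the consensus rules and the reported summary statistics can be
# recomputed and checked without the external dataset.

#' Published fold-wise optimization outcomes on KU-HAR
#'
#' The 10 fold-wise wrapper-optimization results (selected feature serials
#' and the four tuned hyperparameters) reported for each optimizer on the
#' KU-HAR dataset. These are the inputs of the consensus aggregation;
#' feeding them to [finalize_config()] reproduces the published finalized
#' configurations (23 features with 280/0.116176736/7/1 for GJO; 44 features
#' with 230/0.2/6/2 for WARSO).
#'
#' @param optimizer `"gjo"` or `"warso"`.
#' @return list of 10 `fold_outcome`-compatible lists in fold order.
#' @export
kuhar_reference_outcomes <- function(optimizer = c("gjo", "warso")) {
  optimizer <- match.arg(optimizer)
  path <- system.file("extdata", "kuhar_reference_fold_outcomes.csv",
                      package = "haropt", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(learning_rate = "character"))
  df <- df[df$optimizer == optimizer, , drop = FALSE]
  lapply(seq_len(nrow(df)), function(i) {
    structure(
      list(fold = df$fold[i],
           features = as.integer(strsplit(df$features[i], " ", fixed = TRUE)[[1]]),
           n_estimators = df$n_estimators[i],
           learning_rate = as.numeric(df$learning_rate[i]),
           max_depth = df$max_depth[i],
           min_child_weight = df$min_child_weight[i]),
      class = "fold_outcome"
    )
  })
}

#' Published fold-wise test metrics on KU-HAR
#'
#' Per-fold test accuracy, macro F-score, precision and recall (percent) and
#' one-vs-rest AUC reported for the two finalized models over the ten
#' stratified 70/30 splits, plus the fold-1 correct-classification counts.
#'
#' @return `kuhar_reference_metrics()`: data frame with one row per
#'   optimizer and fold; `kuhar_reference_fold1_counts()`: data frame with
#'   the fold-1 correct/total test counts per optimizer.
#' @export
kuhar_reference_metrics <- function() {
  path <- system.file("extdata", "kuhar_reference_fold_metrics.csv",
                      package = "haropt", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname kuhar_reference_metrics
#' @export
kuhar_reference_fold1_counts <- function() {
  path <- system.file("extdata", "kuhar_reference_fold1_counts.csv",
                      package = "haropt", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
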