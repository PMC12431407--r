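# Wrapper fitness: decode a candidate position into (features,
# hyperparameters), train the delegated XGBoost classifier on the inner
# training split of the fold's training partition, and score macro F1 on the
# disjoint inner evaluation split. The fold's held-out 30% test partition is
# never touched during optimization.

#' XGBoost classifier adapter
#'
#' A thin, deterministic boundary around `xgboost::xgb.train()` exposing the
#' four tuned hyperparameters. Training is single-threaded with the
#' histogram tree method (64 bins by default -- ample resolution for smooth
#' window statistics), so a fixed adapter seed gives identical fits.
#'
#' @param n_estimators number of boosting rounds (P1).
#' @param learning_rate shrinkage eta (P2).
#' @param max_depth maximum tree depth (P3).
#' @param min_child_weight minimum child hessian weight (P4).
#' @param nthread training threads (default 1, for determinism).
#' @param seed adapter seed (default 0; fixed across fitness calls so fitness
#'   differences reflect the candidate, not classifier randomness).
#' @param max_bin histogram bins per feature.
#' @return an object of class `xgb_adapter`.
#' @export
xgb_adapter <- function(n_estimators = 100L, learning_rate = 0.1,
                        max_depth = 6L, min_child_weight = 1,
                        nthread = 1L, seed = 0L, max_bin = 64L) {
  structure(
    list(n_estimators = as.integer(n_estimators),
         learning_rate = learning_rate,
         max_depth = as.integer(max_depth),
         min_child_weight = min_child_weight,
         nthread = as.integer(nthread), seed = as.integer(seed),
         max_bin = as.integer(max_bin)),
    class = "xgb_adapter"
  )
}

#' Fit / predict with the XGBoost adapter
#'
#' `adapter_fit()` trains a multiclass softprob model on 0-based integer
#' labels. `adapter_predict()` returns 0-based predicted labels (the argmax
#' of the score rows), `adapter_scores()` the per-class probability matrix
#' (rows summing to 1) and `adapter_margin()` the raw per-class margins
#' (the scale on which Shapley attributions are exact).
#'
#' @param adapter an [xgb_adapter()].
#' @param x numeric feature matrix.
#' @param y integer labels in `0:(n_classes-1)`.
#' @param n_classes number of classes (defaults to `max(y) + 1`).
#' @return `adapter_fit()` an object of class `har_xgb_model`; the others a
#'   label vector or an `n x n_classes` matrix.
#' @export
adapter_fit <- function(adapter, x, y, n_classes = max(y) + 1L) {
  stopifnot(inherits(adapter, "xgb_adapter"), nrow(x) == length(y),
            all(y >= 0L), all(y < n_classes))
  params <- list(
    objective = "multi:softprob",
    num_class = n_classes,
    eta = adapter$learning_rate,
    max_depth = adapter$max_depth,
    min_child_weight = adapter$min_child_weight,
    tree_method = "hist",
    max_bin = adapter$max_bin,
    nthread = adapter$nthread,
    seed = adapter$seed
  )
  booster <- xgboost::xgb.train(
    params = params,
    data = xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = adapter$nthread),
    nrounds = adapter$n_estimators,
    verbose = 0
  )
  structure(
    list(booster = booster, n_classes = n_classes, adapter = adapter,
         feature_names = colnames(x)),
    class = "har_xgb_model"
  )
}

#' @rdname adapter_fit
#' @param model a fitted `har_xgb_model`.
#' @export
adapter_scores <- function(model, x) {
  stopifnot(inherits(model, "har_xgb_model"))
  dm <- xgboost::xgb.DMatrix(as.matrix(x), nthread = model$adapter$nthread)
  matrix(stats::predict(model$booster, dm), ncol = model$n_classes, byrow = FALSE)
}

#' @rdname adapter_fit
#' @export
adapter_predict <- function(model, x) {
  max.col(adapter_scores(model, x)) - 1L
}

#' @rdname adapter_fit
#' @export
adapter_margin <- function(model, x) {
  stopifnot(inherits(model, "har_xgb_model"))
  dm <- xgboost::xgb.DMatrix(as.matrix(x), nthread = model$adapter$nthread)
  matrix(stats::predict(model$booster, dm, outputmargin = TRUE),
         ncol = model$n_classes, byrow = FALSE)
}

#' Prepare the fitness context for one fold
#'
#' Builds the fixed stratified inner split (default 80/20) of the fold's
#' training partition. Every fitness call trains on the inner-train rows and
#' scores macro F1 on the disjoint inner-evaluation rows; the split never
#' changes within a fold, so the fitness landscape is deterministic.
#'
#' @param fold_train a [feature_table()] holding the fold's training
#'   partition (>= 2 classes).
#' @param inner_fraction held-out fraction for fitness evaluation
#'   (default 0.2).
#' @param seed seed for the inner split.
#' @param adapter_args named list of extra [xgb_adapter()] arguments
#'   (e.g. `max_bin`).
#' @return an object of class `fitness_context`.
#' @export
fitness_context <- function(fold_train, inner_fraction = 0.2, seed = 0L,
                            adapter_args = list()) {
  stopifnot(inherits(fold_train, "feature_table"))
  labels <- feature_labels(fold_train)
  if (length(unique(labels)) < 2L) stop("fold training data has a single class")
  split <- stratified_split(labels, inner_fraction, seed)
  values <- feature_values(fold_train)
  structure(
    list(x_train = values[split$train, , drop = FALSE],
         y_train = labels[split$train],
         x_eval = values[split$test, , drop = FALSE],
         y_eval = labels[split$test],
         n_classes = max(labels) + 1L,
         adapter_args = adapter_args),
    class = "fitness_context"
  )
}

#' Fitness of one candidate position
#'
#' Decodes the position, restricts the feature columns to the selected
#' serials, fits the adapter on the inner-train split and returns the macro
#' F1 score on the inner-evaluation split. A classifier failure yields
#' fitness 0 with a warning so the search continues.
#'
#' @param position numeric position of length `4 + n_mask`.
#' @param context a [fitness_context()].
#' @param space the [search_space()] used to decode.
#' @return macro F1 in [0, 1].
#' @export
candidate_fitness <- function(position, context, space) {
  cfg <- decode_position(position, space)
  cols <- cfg$selected + 1L
  tryCatch({
    adapter <- do.call(xgb_adapter, c(
      list(n_estimators = cfg$n_estimators, learning_rate = cfg$learning_rate,
           max_depth = cfg$max_depth, min_child_weight = cfg$min_child_weight),
      context$adapter_args
    ))
    model <- adapter_fit(adapter, context$x_train[, cols, drop = FALSE],
                         context$y_train, context$n_classes)
    pred <- adapter_predict(model, context$x_eval[, cols, drop = FALSE])
    macro_f1(context$y_eval, pred, context$n_classes)
  }, error = function(e) {
    warning("classifier failure treated as fitness 0: ", conditionMessage(e))
    0
  })
}

#' Run the wrapper optimization for one fold
#'
#' Builds the search space over the fold's feature columns, prepares the
#' fitness context (seeded from `(base_seed, fold_index)`), and maximizes
#' [candidate_fitness()] with the configured metaheuristic. Reproducible
#' given `(config$base_seed, fold_index)`.
#'
#' @param fold_train a [feature_table()] with the fold's training partition.
#' @param method `"gjo"` or `"warso"` (defaults to `config$method`).
#' @param config a [run_config()].
#' @param fold_index 1-based fold number.
#' @return an object of class `fold_outcome`: `fold`, sorted 0-based
#'   `features`, `n_estimators`, `learning_rate`, `max_depth`,
#'   `min_child_weight`, best `fitness`, the best-fitness `trajectory`
#'   (length `config$epochs`) and the `evaluations` count.
#' @export
run_fold_optimization <- function(fold_train, method = config$method,
                                  config = run_config(), fold_index = 1L) {
  stopifnot(inherits(fold_train, "feature_table"))
  space <- search_space(n_mask = ncol(feature_values(fold_train)))
  context <- fitness_context(fold_train, config$inner_fraction,
                             seed = derive_seed(config$base_seed, fold_index, 1L))
  result <- optimize_mha(
    function(position) candidate_fitness(position, context, space),
    space, method = method,
    population = config$population, epochs = config$epochs,
    seed = derive_seed(config$base_seed, fold_index, 2L),
    control = list(c1 = config$c1, levy_beta = config$levy_beta,
                   levy_scale = config$levy_scale, alpha = config$alpha,
                   attack_probability = config$attack_probability,
                   weak_relocation = config$weak_relocation)
  )
  cfg <- decode_position(result$best_position, space)
  structure(
    list(fold = as.integer(fold_index),
         features = cfg$selected,
         n_estimators = cfg$n_estimators,
         learning_rate = cfg$learning_rate,
         max_depth = cfg$max_depth,
         min_child_weight = cfg$min_child_weight,
         fitness = result$best_fitness,
         trajectory = result$trajectory,
         evaluations = result$evaluations,
         method = method),
    class = "fold_outcome"
  )
}

#' @export
print.fold_outcome <- function(x, ...) {
  fit <- if (is.null(x$fitness)) "?" else signif(x$fitness, 4)
  cat("<fold_outcome> fold", x$fold, "|", length(x$features), "features | F1",
      fit, "| P1-P4:", x$n_estimators,
      signif(x$learning_rate, 6), x$max_depth, x$min_child_weight, "\n")
  invisible(x)
}
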