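# Shapley-value interpretability.
#
# Two routes: exact_shapley() enumerates all feature subsets and applies the
# classical combinatorial weights (tractable up to 12 features; absent
# features are marginalised by averaging the value function over a background
# set, the interventional convention), and tree_shap()/explain_model()
# delegate to the TreeSHAP algorithm built into XGBoost
# (predict(..., predcontrib = TRUE)), which scales to the full models.
# Multiclass models are explained per class in raw margin space, where the
# efficiency identity base + sum(phi) = f(x) holds exactly.

#' Exact Shapley attribution by subset enumeration
#'
#' For each feature i, phi_i is the weighted average over all subsets S of
#' the remaining features of the marginal contribution v(S + i) - v(S),
#' with weight |S|! (d - |S| - 1)! / d!. The value of a subset is the mean of
#' `value_fn` over the background rows with the subset's columns replaced by
#' the instance's values. Efficiency (base value + sum of contributions =
#' model output) holds by construction up to float round-off.
#'
#' @param value_fn function taking a numeric matrix (rows = inputs) and
#'   returning one model output per row.
#' @param instance numeric vector, the input being explained (at most 12
#'   features; larger models go through [explain_model()]).
#' @param background numeric matrix of reference rows (same width).
#' @return an object of class `attribution`: named `phi`, `base_value`
#'   (mean background output), `fx` (output at `instance`) and
#'   `feature_values`.
#' @export
exact_shapley <- function(value_fn, instance, background) {
  d <- length(instance)
  if (d > 12L) {
    stop("exact enumeration supports at most 12 features; ",
         "use explain_model() for larger models")
  }
  background <- as.matrix(background)
  stopifnot(ncol(background) == d, nrow(background) >= 1)
  n_mask <- bitwShiftL(1L, d)
  bits <- bitwShiftL(1L, 0:(d - 1L))
  masks <- 0:(n_mask - 1L)
  popcount <- integer(n_mask)
  v <- numeric(n_mask)
  for (m in masks) {
    mat <- background
    on_bits <- which(bitwAnd(m, bits) != 0L)
    for (j in on_bits) mat[, j] <- instance[j]
    popcount[m + 1L] <- length(on_bits)
    v[m + 1L] <- mean(value_fn(mat))
  }
  w <- factorial(0:(d - 1L)) * factorial(d - 1L - 0:(d - 1L)) / factorial(d)
  phi <- numeric(d)
  for (j in seq_len(d)) {
    bit <- bits[j]
    without <- masks[bitwAnd(masks, bit) == 0L]
    s <- popcount[without + 1L]
    phi[j] <- sum(w[s + 1L] * (v[without + bit + 1L] - v[without + 1L]))
  }
  names(phi) <- colnames(background) %||% paste0("f", 0:(d - 1L))
  attribution(phi, base_value = v[1L], fx = v[n_mask],
              feature_values = instance)
}

#' Construct (and validate) an attribution
#'
#' @param phi named per-feature contributions.
#' @param base_value expected model output over the background.
#' @param fx model output at the explained instance.
#' @param feature_values the explained instance.
#' @param tol efficiency tolerance (default 1e-6).
#' @return an object of class `attribution`.
#' @export
attribution <- function(phi, base_value, fx, feature_values = NULL,
                        tol = 1e-6) {
  gap <- abs(base_value + sum(phi) - fx)
  if (gap > tol) {
    stop("efficiency violated: |base + sum(phi) - f(x)| = ",
         format(gap, digits = 4))
  }
  structure(
    list(phi = phi, base_value = base_value, fx = fx,
         feature_values = feature_values),
    class = "attribution"
  )
}

#' @export
print.attribution <- function(x, ...) {
  cat("<attribution> base", signif(x$base_value, 5), "+ sum(phi)",
      signif(sum(x$phi), 5), "= f(x)", signif(x$fx, 5), "\n")
  top <- sort(abs(x$phi), decreasing = TRUE)
  show <- names(top)[seq_len(min(5, length(top)))]
  for (f in show) cat(sprintf("  %-16s %+9.4f\n", f, x$phi[[f]]))
  invisible(x)
}

#' TreeSHAP contributions from a fitted model
#'
#' Delegates to XGBoost's built-in TreeSHAP (`predcontrib = TRUE`). For the
#' package's multiclass `har_xgb_model` the result is per class in raw margin
#' space; a plain regression/binary `xgb.Booster` is also accepted.
#'
#' @param model a `har_xgb_model` (see [adapter_fit()]) or an `xgb.Booster`.
#' @param x numeric matrix of instances to explain.
#' @return list with `phi` (`n x d` matrix, or `n x n_classes x d` array for
#'   multiclass), `base_values` (vector, or `n x n_classes`) and `output`
#'   (margin predictions on the same shape).
#' @export
tree_shap <- function(model, x) {
  x <- as.matrix(x)
  if (inherits(model, "har_xgb_model")) {
    dm <- xgboost::xgb.DMatrix(x, nthread = model$adapter$nthread)
    pc <- stats::predict(model$booster, dm, predcontrib = TRUE)
    d <- ncol(x)
    stopifnot(length(dim(pc)) == 3L, dim(pc)[3] == d + 1L)
    phi <- pc[, , seq_len(d), drop = FALSE]
    base <- matrix(pc[, , d + 1L], nrow = dim(pc)[1])
    out <- adapter_margin(model, x)
    list(phi = phi, base_values = base, output = out)
  } else if (inherits(model, "xgb.Booster")) {
    dm <- xgboost::xgb.DMatrix(x)
    pc <- stats::predict(model, dm, predcontrib = TRUE)
    d <- ncol(x)
    stopifnot(ncol(pc) == d + 1L)
    list(phi = pc[, seq_len(d), drop = FALSE],
         base_values = pc[, d + 1L],
         output = stats::predict(model, dm, outputmargin = TRUE))
  } else {
    stop("unsupported model type: ", paste(class(model), collapse = "/"))
  }
}

#' Explain model predictions for a set of instances
#'
#' Computes TreeSHAP attributions for every instance and class, asserts the
#' efficiency identity against the model's raw margin output, and packages
#' the result for ranking and per-instance reports.
#'
#' @param model a fitted `har_xgb_model`.
#' @param instances numeric matrix of rows to explain (columns must match the
#'   features the model was trained on).
#' @param tol efficiency tolerance (default 1e-4 on margins, which are
#'   single-precision inside XGBoost).
#' @return an object of class `shap_explanation`: `phi`
#'   (`n x n_classes x d`), `base_values` (`n x n_classes`), `output`
#'   (`n x n_classes` margins), `predicted` (0-based argmax labels) and
#'   `feature_names`.
#' @export
explain_model <- function(model, instances, tol = 1e-4) {
  stopifnot(inherits(model, "har_xgb_model"))
  instances <- as.matrix(instances)
  ts <- tree_shap(model, instances)
  recon <- unname(apply(ts$phi, c(1, 2), sum)) + ts$base_values
  gap <- max(abs(recon - ts$output))
  if (gap > tol) {
    stop("efficiency violated for delegated attributions: max gap ",
         format(gap, digits = 4))
  }
  feature_names <- model$feature_names %||% paste0("f", seq_len(dim(ts$phi)[3]) - 1L)
  structure(
    list(phi = ts$phi, base_values = ts$base_values, output = ts$output,
         predicted = max.col(ts$output) - 1L,
         feature_names = feature_names),
    class = "shap_explanation"
  )
}

#' Rank features by mean absolute Shapley value
#'
#' @param explanation a `shap_explanation` from [explain_model()].
#' @param by_class if `TRUE`, return one ranking per class; otherwise sum
#'   |phi| over classes before averaging over instances (default).
#' @return data frame with `serial` (0-based), `feature` and
#'   `mean_abs_shap`, sorted decreasing with ties broken by serial; or a list
#'   of such data frames when `by_class = TRUE`.
#' @export
rank_features <- function(explanation, by_class = FALSE) {
  stopifnot(inherits(explanation, "shap_explanation"))
  one <- function(mat_abs) {
    score <- colMeans(mat_abs)
    ord <- order(-score, seq_along(score))
    data.frame(serial = ord - 1L,
               feature = explanation$feature_names[ord],
               mean_abs_shap = score[ord], row.names = NULL)
  }
  if (by_class) {
    ks <- seq_len(dim(explanation$phi)[2])
    stats::setNames(
      lapply(ks, function(k) one(abs(explanation$phi[, k, , drop = FALSE][, 1, ]))),
      paste0("class_", ks - 1L)
    )
  } else {
    one(apply(abs(explanation$phi), c(1, 3), sum))
  }
}

#' Per-instance decision report (correct or misclassified)
#'
#' Mirrors the decision/waterfall reading of a single prediction: the
#' per-class margin decomposition, the predicted class (argmax of the margin
#' decompositions), and the top signed feature contributors for the predicted
#' class and, when a true label is supplied and differs, for the true class
#' -- the template used to analyse misclassifications.
#'
#' @param model a fitted `har_xgb_model`.
#' @param instance numeric vector (one row of the model's feature matrix).
#' @param true_class optional 0-based true label.
#' @param top_n contributors to list per class (default 10).
#' @return list with `predicted`, `true_class`, `per_class` (data frame of
#'   base value, sum of contributions and margin f(x) per class) and
#'   `contributors` (named list of data frames, one per reported class).
#' @export
explain_instance <- function(model, instance, true_class = NULL, top_n = 10L) {
  ex <- explain_model(model, matrix(instance, nrow = 1))
  k <- dim(ex$phi)[2]
  per_class <- data.frame(
    class = 0:(k - 1L),
    base_value = as.numeric(ex$base_values[1, ]),
    sum_phi = vapply(seq_len(k), function(j) sum(ex$phi[1, j, ]), numeric(1)),
    fx = as.numeric(ex$output[1, ])
  )
  predicted <- ex$predicted[1]
  report_classes <- unique(c(predicted, true_class))
  contributors <- lapply(report_classes, function(cl) {
    phi <- ex$phi[1, cl + 1L, ]
    ord <- order(-abs(phi), seq_along(phi))[seq_len(min(top_n, length(phi)))]
    data.frame(feature = ex$feature_names[ord],
               value = instance[ord], phi = phi[ord], row.names = NULL)
  })
  names(contributors) <- paste0("class_", report_classes)
  list(predicted = predicted, true_class = true_class,
       per_class = per_class, contributors = contributors)
}
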