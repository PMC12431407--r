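# Shapley attribution: exact enumeration axioms and TreeSHAP delegation.

test_that("exact Shapley satisfies the dummy and additivity properties", {
  bg <- matrix(rnorm(50 * 3, sd = 2), 50, 3)
  # value depends only on the second feature
  f2 <- function(X) X[, 2]
  at <- exact_shapley(f2, instance = c(4, -1, 9), background = bg)
  expect_equal(unname(at$phi[c(1, 3)]), c(0, 0))
  expect_equal(unname(at$phi[2]), -1 - mean(bg[, 2]))

  # additive game with a zero-mean background: phi recovers the summands
  bg0 <- rbind(c(1, -1), c(-1, 1), c(2, -2), c(-2, 2))
  add <- function(X) X[, 1] + X[, 2]
  at2 <- exact_shapley(add, instance = c(3, 7), background = bg0)
  expect_equal(unname(at2$phi), c(3, 7))
  expect_equal(at2$base_value, 0)
  expect_equal(at2$fx, 10)
})

test_that("the subset weights form a probability distribution", {
  # d = 3: weights over |S| in {0, 1, 2} with choose(2, s) subsets each
  d <- 3
  w <- factorial(0:(d - 1)) * factorial(d - 1 - 0:(d - 1)) / factorial(d)
  expect_equal(w, c(2 / 6, 1 / 6, 2 / 6))
  expect_equal(sum(choose(d - 1, 0:(d - 1)) * w), 1)
})

test_that("symmetric features receive equal attributions", {
  bg <- cbind(a = c(1, -1, 0.5, -0.5), b = c(1, -1, 0.5, -0.5), c = rnorm(4))
  sym <- function(X) (X[, 1] + X[, 2])^2
  at <- exact_shapley(sym, instance = c(2, 2, 5), background = bg)
  expect_equal(unname(at$phi[1]), unname(at$phi[2]), tolerance = 1e-12)
})

test_that("efficiency holds for random games and is enforced", {
  set.seed(41)
  for (i in 1:20) {
    d <- sample(2:6, 1)
    A <- matrix(rnorm(d * d), d)
    g <- function(X) rowSums((X %*% A)^2) - X[, 1]
    bg <- matrix(rnorm(8 * d), 8, d)
    inst <- rnorm(d)
    at <- exact_shapley(g, inst, bg)
    expect_equal(at$base_value + sum(at$phi), at$fx, tolerance = 1e-9)
  }
  expect_error(attribution(phi = c(1, 1), base_value = 0, fx = 5),
               "efficiency")
  expect_error(exact_shapley(function(X) X[, 1], rnorm(13),
                             matrix(rnorm(26), 2, 13)),
               "at most 12")
})

# -- TreeSHAP delegation -----------------------------------------------------
# A full 2^8 factorial design makes every tree node population a product set,
# so the path-dependent TreeSHAP expectations coincide with interventional
# background averaging and the two routes must agree.

factorial_design <- as.matrix(expand.grid(rep(list(c(-1, 1)), 8)))
colnames(factorial_design) <- paste0("x", 1:8)
set.seed(55)
factorial_y <- factorial_design[, 1] * 2 +
  factorial_design[, 2] * factorial_design[, 3] +
  0.5 * factorial_design[, 4] + rnorm(256, sd = 0.1)
toy_booster <- xgboost::xgb.train(
  params = list(objective = "reg:squarederror", max_depth = 3, eta = 0.3,
                nthread = 1),
  data = xgboost::xgb.DMatrix(factorial_design, label = factorial_y, nthread = 1),
  nrounds = 25, verbose = 0
)

test_that("delegated TreeSHAP agrees with exact enumeration on a toy model", {
  value_fn <- function(X) {
    stats::predict(toy_booster, xgboost::xgb.DMatrix(X, nthread = 1))
  }
  ts <- tree_shap(toy_booster, factorial_design[c(1, 100, 256), ])
  for (r in 1:3) {
    inst <- factorial_design[c(1, 100, 256), ][r, ]
    ex <- exact_shapley(value_fn, inst, factorial_design)
    expect_lt(max(abs(ex$phi - ts$phi[r, ])), 1e-4)
    expect_lt(abs(ex$base_value - ts$base_values[r]), 1e-4)
    # efficiency of the delegated route against the raw model output
    expect_equal(sum(ts$phi[r, ]) + ts$base_values[r], ts$output[r],
                 tolerance = 1e-5)
  }
})

# -- multiclass explanation pipeline ----------------------------------------

shap_tbl <- make_benchmark_features(360, 10, k_informative = 4,
                                    class_separation = 1.2, n_classes = 3,
                                    seed = 17)
shap_split <- make_folds(feature_labels(shap_tbl), 1, 0.3, 21)[[1]]
shap_model <- adapter_fit(
  xgb_adapter(n_estimators = 50, learning_rate = 0.2, max_depth = 3,
              min_child_weight = 1),
  feature_values(shap_tbl)[shap_split$train, ],
  feature_labels(shap_tbl)[shap_split$train]
)
shap_test_x <- feature_values(shap_tbl)[shap_split$test, ]
shap_test_y <- feature_labels(shap_tbl)[shap_split$test]

test_that("multiclass explanations satisfy efficiency and argmax consistency", {
  ex <- explain_model(shap_model, shap_test_x[1:30, ])
  expect_equal(dim(ex$phi), c(30, 3, 10))
  recon <- unname(apply(ex$phi, c(1, 2), sum)) + ex$base_values
  expect_equal(recon, ex$output, tolerance = 1e-4, ignore_attr = TRUE)
  expect_identical(ex$predicted, adapter_predict(shap_model, shap_test_x[1:30, ]))
})

test_that("feature ranking surfaces the class-informative columns", {
  # a model trained on two informative columns only
  x <- matrix(rnorm(400 * 10), 400, 10)
  y <- rep(0:1, each = 200)
  x[, 3] <- x[, 3] + 2 * y   # serial 2
  x[, 8] <- x[, 8] - 2 * y   # serial 7
  model <- adapter_fit(xgb_adapter(n_estimators = 40, learning_rate = 0.3,
                                   max_depth = 3, min_child_weight = 1),
                       x, y, n_classes = 2L)
  ex <- explain_model(model, x[seq(1, 400, by = 8), ])
  rk <- rank_features(ex)
  expect_setequal(rk$serial[1:2], c(2L, 7L))
  # ranking is invariant to instance order
  ex_rev <- explain_model(model, x[rev(seq(1, 400, by = 8)), ])
  expect_equal(rank_features(ex_rev), rk)
})

test_that("single-prediction reports expose per-class decompositions", {
  pred <- adapter_predict(shap_model, shap_test_x)
  wrong <- which(pred != shap_test_y)
  idx <- if (length(wrong)) wrong[1] else 1L
  rep_ <- explain_instance(shap_model, shap_test_x[idx, ],
                           true_class = shap_test_y[idx], top_n = 5)
  expect_equal(rep_$predicted, pred[idx])
  expect_equal(nrow(rep_$per_class), 3)
  # the predicted class is the argmax of the margin decompositions
  expect_equal(rep_$per_class$class[which.max(rep_$per_class$fx)],
               rep_$predicted)
  expect_equal(rep_$per_class$base_value + rep_$per_class$sum_phi,
               rep_$per_class$fx, tolerance = 1e-4)
  # misclassification template: contributions for predicted AND true class
  if (length(wrong)) {
    expect_setequal(names(rep_$contributors),
                    paste0("class_", c(pred[idx], shap_test_y[idx])))
  }
  expect_equal(nrow(rep_$contributors[[1]]), 5)
})
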