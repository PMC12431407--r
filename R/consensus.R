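# Consensus aggregation of fold-wise optimization outcomes: each
# hyperparameter takes the value occurring most often across folds (modal
# ties and the all-distinct case both resolve to the value whose first
# occurrence is earliest in fold order), and the final feature set is the
# union of the fold-wise selections.

#' Majority vote over per-fold values
#'
#' Returns the mode of `values`. When several values tie for the highest
#' count, the one whose first occurrence is earliest in fold order wins; when
#' all values are distinct this reduces to the fold-1 value. Floating-point
#' values are compared exactly (repeats arise only from bound clamping).
#'
#' @param values non-empty vector in fold order.
#' @return the winning value.
#' @export
#' @examples
#' majority_vote(c(225, 219, 233, 214, 254, 230, 208, 211, 230, 211))  # 230
majority_vote <- function(values) {
  stopifnot(length(values) >= 1)
  ux <- unique(values)                       # first-occurrence order
  counts <- vapply(ux, function(v) sum(values == v), numeric(1))
  ux[which.max(counts)]                      # which.max takes the earliest max
}

#' Union of fold-wise feature selections
#'
#' @param fold_feature_sets list of integer vectors of 0-based feature
#'   serials.
#' @return sorted integer vector of the union.
#' @export
union_features <- function(fold_feature_sets) {
  sort(unique(unlist(lapply(fold_feature_sets, as.integer))))
}

#' Consolidate fold outcomes into one final configuration
#'
#' Features are the union of the fold-wise selections; each hyperparameter is
#' the [majority_vote()] over folds. Fold order matters only through the
#' modal-tie / all-distinct fallback, so outcomes must carry their fold index
#' and be supplied in fold order.
#'
#' @param outcomes list of `fold_outcome` objects (or compatible lists) in
#'   fold order.
#' @return an object of class `final_config`: sorted 0-based `features`,
#'   `n_features`, `n_estimators`, `learning_rate`, `max_depth`,
#'   `min_child_weight`.
#' @export
finalize_config <- function(outcomes) {
  stopifnot(length(outcomes) >= 1)
  folds <- vapply(outcomes, function(o) {
    if (is.null(o$fold)) stop("fold index metadata missing; the vote fallback depends on fold order")
    as.integer(o$fold)
  }, integer(1))
  if (is.unsorted(folds, strictly = TRUE)) {
    stop("outcomes must be supplied in increasing fold order")
  }
  features <- union_features(lapply(outcomes, `[[`, "features"))
  grab <- function(field) vapply(outcomes, function(o) as.numeric(o[[field]]), numeric(1))
  structure(
    list(features = features,
         n_features = length(features),
         n_estimators = as.integer(majority_vote(grab("n_estimators"))),
         learning_rate = majority_vote(grab("learning_rate")),
         max_depth = as.integer(majority_vote(grab("max_depth"))),
         min_child_weight = as.integer(majority_vote(grab("min_child_weight")))),
    class = "final_config"
  )
}

#' @export
print.final_config <- function(x, ...) {
  cat("<final_config>", x$n_features, "features | n_estimators", x$n_estimators,
      "| learning_rate", signif(x$learning_rate, 9), "| max_depth", x$max_depth,
      "| min_child_weight", x$min_child_weight, "\n  features: ",
      paste(x$features, collapse = ", "), "\n", sep = " ")
  invisible(x)
}
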