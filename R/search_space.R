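# The mixed hyperparameter + feature-mask search space.
#
# 52 dimensions by default: P1 n_estimators (integer 100-300), P2
# learning_rate (real 0.001-0.2), P3 max_depth (integer 3-7), P4
# min_child_weight (integer 1-10), then one continuous mask dimension in
# [0, 1] per candidate feature. Optimizer dynamics stay continuous; the
# integer rounding and 0.5 mask threshold are applied only at decode time.

#' Construct the optimizer search space
#'
#' @param n_mask number of feature-mask dimensions (default 48).
#' @param n_estimators,learning_rate,max_depth,min_child_weight length-2
#'   numeric `c(lower, upper)` bounds for the four classifier
#'   hyperparameters.
#' @return an object of class `search_space` with elements `lower`, `upper`
#'   (length `4 + n_mask`) and `n_mask`.
#' @export
search_space <- function(n_mask = 48L,
                         n_estimators = c(100, 300),
                         learning_rate = c(0.001, 0.2),
                         max_depth = c(3, 7),
                         min_child_weight = c(1, 10)) {
  n_mask <- as.integer(n_mask)
  stopifnot(n_mask >= 1)
  lower <- c(n_estimators[1], learning_rate[1], max_depth[1],
             min_child_weight[1], rep(0, n_mask))
  upper <- c(n_estimators[2], learning_rate[2], max_depth[2],
             min_child_weight[2], rep(1, n_mask))
  if (any(lower > upper)) stop("lower bound exceeds upper bound")
  structure(
    list(lower = lower, upper = upper, n_mask = n_mask,
         integer_dims = c(TRUE, FALSE, TRUE, TRUE, rep(FALSE, n_mask))),
    class = "search_space"
  )
}

#' Generic bounded continuous space (for benchmark objectives)
#'
#' A plain box without hyperparameter/mask semantics; usable with
#' [optimize_mha()], [init_position()] and [clamp_position()] (but not
#' [decode_position()]).
#'
#' @param lower,upper numeric bound vectors of equal length.
#' @return an object of class `search_space` with `n_mask = 0`.
#' @export
box_space <- function(lower, upper) {
  stopifnot(length(lower) == length(upper), all(lower <= upper))
  structure(
    list(lower = as.numeric(lower), upper = as.numeric(upper), n_mask = 0L,
         integer_dims = rep(FALSE, length(lower))),
    class = "search_space"
  )
}

#' @export
print.search_space <- function(x, ...) {
  cat("<search_space>", length(x$lower), "dims: 4 hyperparameters +",
      x$n_mask, "mask dims\n")
  invisible(x)
}

#' Draw a uniform random position within the space bounds
#'
#' Each coordinate is `lower + U(0,1) * (upper - lower)`; uses the current
#' RNG stream (callers seed via [with_seed()] / [optimize_mha()]).
#'
#' @param space a [search_space()].
#' @return numeric position vector.
#' @export
init_position <- function(space) {
  d <- length(space$lower)
  space$lower + stats::runif(d) * (space$upper - space$lower)
}

#' Project a position onto the box bounds
#'
#' Elementwise min/max clamp; idempotent. Non-finite coordinates are replaced
#' by a fresh uniform draw within their bounds (with a warning).
#'
#' @param position numeric vector of length `4 + n_mask`.
#' @param space a [search_space()].
#' @return clamped position.
#' @export
clamp_position <- function(position, space) {
  bad <- !is.finite(position)
  if (any(bad)) {
    warning("replacing ", sum(bad), " non-finite coordinate(s) with uniform draws")
    position[bad] <- space$lower[bad] +
      stats::runif(sum(bad)) * (space$upper[bad] - space$lower[bad])
  }
  pmin(pmax(position, space$lower), space$upper)
}

#' Decode a continuous position into a trainable classifier configuration
#'
#' Integer hyperparameters are rounded to the nearest integer and clamped to
#' their bounds; the learning rate is clamped to its real bounds. Mask
#' dimension d selects feature serial d-1 when its coordinate is >= 0.5. An
#' all-below-threshold mask is repaired by selecting the single dimension
#' with the largest mask value (ties resolved to the lowest serial), so every
#' decoded configuration is trainable.
#'
#' @param position finite numeric vector of length `4 + n_mask`.
#' @param space a [search_space()].
#' @return an object of class `decoded_config`: `n_estimators`,
#'   `learning_rate`, `max_depth`, `min_child_weight`, logical `mask`, and
#'   the sorted 0-based `selected` feature serials (never empty).
#' @export
decode_position <- function(position, space) {
  stopifnot(length(position) == length(space$lower), all(is.finite(position)))
  clamp1 <- function(v, i) min(max(v, space$lower[i]), space$upper[i])
  p1 <- as.integer(clamp1(round(position[1]), 1))
  p2 <- clamp1(position[2], 2)
  p3 <- as.integer(clamp1(round(position[3]), 3))
  p4 <- as.integer(clamp1(round(position[4]), 4))
  maskv <- position[-(1:4)]
  mask <- maskv >= 0.5
  if (!any(mask)) mask[which.max(maskv)] <- TRUE  # repair: argmax, ties -> lowest
  structure(
    list(n_estimators = p1, learning_rate = p2, max_depth = p3,
         min_child_weight = p4, mask = mask,
         selected = which(mask) - 1L),
    class = "decoded_config"
  )
}

#' @export
print.decoded_config <- function(x, ...) {
  cat("<decoded_config> n_estimators", x$n_estimators,
      "| learning_rate", signif(x$learning_rate, 6),
      "| max_depth", x$max_depth,
      "| min_child_weight", x$min_child_weight, "\n  features (",
      length(x$selected), "): ", paste(x$selected, collapse = ", "), "\n", sep = "")
  invisible(x)
}
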