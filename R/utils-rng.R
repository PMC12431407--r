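# Seed handling: every stochastic entry point takes an explicit seed and runs
# under with_seed(), which restores the caller's RNG state afterwards, so the
# package never leaks changes into the global stream.

#' Evaluate code under a fixed RNG seed, restoring the caller's stream
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Derive a reproducible child seed from a base seed and index path
#'
#' Deterministic mixing of a base seed with one or more integer indices
#' (fold number, stage number, ...). The result always fits a 32-bit R
#' integer, so it is safe to hand to [set.seed()] on any platform.
#'
#' @param base integer base seed.
#' @param ... integer indices identifying the consumer (e.g. fold, stage).
#' @return a single non-negative integer seed.
#' @export
#' @examples
#' derive_seed(42, 3)      # fold-3 stream of base seed 42
#' derive_seed(42, 3, 1)   # a sub-stream of that
derive_seed <- function(base, ...) {
  idx <- c(...)
  stopifnot(length(base) == 1L, is.finite(base))
  s <- as.double(base) %% 2147483647
  for (k in idx) {
    s <- (s * 69069 + as.double(k) * 1234567 + 1) %% 2147483647
  }
  as.integer(s)
}
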