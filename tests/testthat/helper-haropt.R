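# Shared helpers for the haropt test suite. Fixtures are generated in code;
# nothing is read from disk except the package's own reference CSVs.

# Excess-kurtosis-free sample kurtosis (normal ~ 3).
sample_kurtosis <- function(x) {
  m <- mean(x)
  mean((x - m)^4) / mean((x - m)^2)^2
}

# Independent per-sample implementation of the macro metrics (oracle for
# metrics_from_confusion): loops over samples and classes directly.
brute_metrics <- function(true, pred, n_classes) {
  per <- sapply(0:(n_classes - 1L), function(c) {
    tp <- sum(true == c & pred == c)
    fp <- sum(true != c & pred == c)
    fn <- sum(true == c & pred != c)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p = p, r = r, f = f)
  })
  list(accuracy = 100 * mean(true == pred),
       precision = 100 * mean(per["p", ]),
       recall = 100 * mean(per["r", ]),
       fscore = 100 * mean(per["f", ]))
}

# O(n^2) pairwise-comparison one-vs-rest AUC (oracle for ovr_auc).
brute_ovr_auc <- function(true, scores) {
  aucs <- c()
  for (c in 0:(ncol(scores) - 1L)) {
    pos <- which(true == c)
    neg <- which(true != c)
    if (!length(pos) || !length(neg)) next
    s <- scores[, c + 1L]
    total <- 0
    for (i in pos) total <- total + sum(s[i] > s[neg]) + 0.5 * sum(s[i] == s[neg])
    aucs <- c(aucs, total / (length(pos) * length(neg)))
  }
  mean(aucs)
}

# A tiny KU-HAR-like record for IO round trips.
make_record <- function(serial, class_id = 3L, channel_length = 5L, seed = serial) {
  set.seed(seed)
  chans <- lapply(har_channel_names(), function(ch) round(rnorm(channel_length), 6))
  names(chans) <- har_channel_names()
  structure(
    c(chans, list(class_id = as.integer(class_id),
                  channel_length = as.integer(channel_length),
                  serial = as.integer(serial))),
    class = "kuhar_record"
  )
}

# A quick trainable position over a d-feature space: moderate hyperparameters
# with the given mask bits switched on.
quick_position <- function(d, on = seq_len(d) - 1L,
                           p1 = 100, p2 = 0.15, p3 = 4, p4 = 2) {
  mask <- rep(0, d)
  mask[on + 1L] <- 1
  c(p1, p2, p3, p4, mask)
}
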