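# Synthetic data generators.
#
# Two layers: (1) a signal-space generator emulating the KU-HAR structure --
# 18 activity classes, 6 channels sampled at 100 Hz, each channel a noisy
# sinusoid x(t) = m + a*sin(2*pi*f*t/rate + phi) + eps with class-dependent
# baseline m, amplitude a, frequency f and noise sd; static/transition
# classes have a = 0; (2) a feature-space benchmark generator with a known
# set of informative columns, so optimizer behaviour can be tested without
# going through feature extraction.

#' Construct an activity model for the signal generator
#'
#' All per-class/per-channel parameters are matrices of shape
#' `n_classes x 6` (channel order [har_channel_names()]).
#'
#' @param baseline,amplitude,frequency,noise_sd numeric matrices
#'   (`n_classes` x 6): per-channel signal baseline (signal units), sinusoid
#'   amplitude, frequency (Hz, below the Nyquist rate) and Gaussian noise sd.
#' @param window_length samples per channel (default 300).
#' @param sample_rate Hz (default 100).
#' @return an object of class `activity_model`.
#' @seealso [default_activity_model()]
#' @export
activity_model <- function(baseline, amplitude, frequency, noise_sd,
                           window_length = 300L, sample_rate = 100) {
  baseline <- as.matrix(baseline); amplitude <- as.matrix(amplitude)
  frequency <- as.matrix(frequency); noise_sd <- as.matrix(noise_sd)
  n_classes <- nrow(baseline)
  stopifnot(n_classes >= 2, ncol(baseline) == 6,
            all(dim(amplitude) == dim(baseline)),
            all(dim(frequency) == dim(baseline)),
            all(dim(noise_sd) == dim(baseline)),
            all(noise_sd >= 0), all(amplitude >= 0),
            all(frequency >= 0), all(frequency < sample_rate / 2),
            window_length >= 1)
  structure(
    list(baseline = baseline, amplitude = amplitude, frequency = frequency,
         noise_sd = noise_sd, n_classes = n_classes,
         window_length = as.integer(window_length), sample_rate = sample_rate),
    class = "activity_model"
  )
}

#' Default 18-class activity model mirroring the KU-HAR class mix
#'
#' Classes 0-6 emulate static postures and postural transitions (zero
#' amplitude, distinct channel baselines, gravity on the accelerometer Z
#' axis); classes 7-17 are dynamic activities with class-specific oscillation
#' frequencies (0.8-5.75 Hz, walking to running/jumping cadence range),
#' larger accelerometer amplitudes and heavier noise. Baselines are spread
#' across classes so that window statistics separate the classes.
#'
#' @param n_classes number of classes (default 18; the first
#'   `min(7, n_classes)` are static).
#' @param window_length,sample_rate see [activity_model()].
#' @return an `activity_model`.
#' @export
default_activity_model <- function(n_classes = 18L, window_length = 300L,
                                   sample_rate = 100) {
  n_classes <- as.integer(n_classes)
  stopifnot(n_classes >= 2)
  cls <- seq_len(n_classes) - 1L
  gravity <- c(0, 0, 9.81, 0, 0, 0)
  spread <- c(1, -0.8, 0.6, -0.4, 0.9, -0.7)
  baseline <- outer(cls, spread, function(c, w) 0.4 * c * w) +
    matrix(gravity, n_classes, 6, byrow = TRUE)
  n_static <- min(7L, n_classes)
  dynamic <- cls >= n_static
  amplitude <- matrix(0, n_classes, 6)
  frequency <- matrix(0, n_classes, 6)
  noise_sd <- matrix(0.08, n_classes, 6)
  if (any(dynamic)) {
    d_idx <- which(dynamic)
    d_rank <- seq_along(d_idx) - 1L
    base_freq <- 0.8 + 0.45 * d_rank
    chan_mult <- 1 + 0.05 * (seq_len(6) - 1)
    frequency[d_idx, ] <- outer(base_freq, chan_mult)
    amp_acc <- 2.0 + 0.30 * d_rank
    amp_gyr <- 1.0 + 0.20 * d_rank
    amplitude[d_idx, 1:3] <- amp_acc
    amplitude[d_idx, 4:6] <- amp_gyr
    noise_sd[d_idx, ] <- 0.30
  }
  activity_model(baseline, amplitude, frequency, noise_sd,
                 window_length = window_length, sample_rate = sample_rate)
}

#' Simulate one labelled signal window
#'
#' Channel j of a class-c window is
#' `x(t) = m_cj + a_cj * sin(2*pi*f_cj*t/rate + phi) + eps_t` with one phase
#' `phi ~ U(0, 2*pi)` drawn per window and `eps_t ~ N(0, sd_cj^2)`.
#'
#' @param model an [activity_model()].
#' @param class_id integer class in `0:(n_classes-1)`.
#' @param seed integer seed for this window.
#' @return a [signal_window()].
#' @export
simulate_window <- function(model, class_id, seed) {
  stopifnot(inherits(model, "activity_model"))
  if (!(class_id %in% (seq_len(model$n_classes) - 1L))) {
    stop("class_id ", class_id, " outside 0-", model$n_classes - 1L)
  }
  with_seed(seed, {
    r <- class_id + 1L
    tt <- seq_len(model$window_length) - 1L
    phi <- stats::runif(1, 0, 2 * pi)
    chans <- lapply(seq_len(6), function(j) {
      model$baseline[r, j] +
        model$amplitude[r, j] *
          sin(2 * pi * model$frequency[r, j] * tt / model$sample_rate + phi) +
        stats::rnorm(model$window_length, 0, model$noise_sd[r, j])
    })
    names(chans) <- har_channel_names()
    signal_window(chans, class_id, model$sample_rate)
  })
}

#' Simulate a class-balanced labelled dataset of windows
#'
#' Deterministic given `seed`: window k of class c uses the derived seed
#' `derive_seed(seed, c, k)`.
#'
#' @param model an [activity_model()].
#' @param n_per_class windows per class (>= 1).
#' @param seed master seed.
#' @return list of `n_classes * n_per_class` [signal_window()] objects,
#'   grouped by class.
#' @export
simulate_dataset <- function(model, n_per_class, seed) {
  stopifnot(n_per_class >= 1)
  out <- vector("list", model$n_classes * n_per_class)
  i <- 0L
  for (c in seq_len(model$n_classes) - 1L) {
    for (k in seq_len(n_per_class)) {
      i <- i + 1L
      out[[i]] <- simulate_window(model, c, derive_seed(seed, c, k))
    }
  }
  out
}

#' Generate a feature-space benchmark table with known informative columns
#'
#' All columns are unit-variance Gaussian noise. For each of `k_informative`
#' randomly chosen columns, class means are placed on an equally spaced grid
#' with adjacent classes `class_separation` within-class standard deviations
#' apart; the class-to-grid assignment is a fresh random permutation per
#' column, so different informative columns discriminate different class
#' pairs. The chosen 0-based column serials are recorded in the table's
#' `informative` metadata.
#'
#' @param n_samples total rows (split as evenly as possible over classes).
#' @param n_features number of columns (default 48).
#' @param k_informative number of class-dependent columns
#'   (`1 <= k_informative <= n_features`).
#' @param class_separation effect size in within-class sd units (>= 0).
#' @param n_classes number of classes (default 6: the 18-class application at
#'   reduced scale, and enough classes that no 2-3-column subset makes the
#'   problem trivially separable -- a requirement for the table to exercise
#'   feature-subset recovery).
#' @param seed integer seed.
#' @return a [feature_table()] with `informative` metadata (0-based serials).
#' @export
make_benchmark_features <- function(n_samples, n_features = 48L,
                                    k_informative, class_separation,
                                    n_classes = 6L, seed = 1L) {
  stopifnot(k_informative >= 1, k_informative <= n_features,
            n_classes >= 2, n_samples >= n_classes, class_separation >= 0)
  with_seed(seed, {
    base <- n_samples %/% n_classes
    extra <- n_samples %% n_classes
    counts <- rep(base, n_classes) + c(rep(1L, extra), rep(0L, n_classes - extra))
    labels <- rep(seq_len(n_classes) - 1L, counts)
    values <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
    informative <- sort(sample.int(n_features, k_informative)) - 1L
    for (j in informative) {
      perm <- sample.int(n_classes) - 1L   # class -> grid position
      centers <- class_separation * perm
      centers <- centers - mean(centers)
      values[, j + 1L] <- values[, j + 1L] + centers[labels + 1L]
    }
    feature_table(values, labels, informative = informative)
  })
}
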