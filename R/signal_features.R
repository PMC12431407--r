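# Statistical feature extraction for 6-channel inertial windows.
#
# Each sensor channel (accelerometer X/Y/Z in m/s^2, gyroscope X/Y/Z in rad/s)
# is summarised by eight statistics: mean, median, RMS, min, max, standard
# deviation, range and mean absolute deviation. SD and MAD use the population
# (1/n) normalisation. 8 statistics x 6 channels = 48 features per window.

#' Canonical channel names, statistic names and feature names
#'
#' The 48 feature names follow the canonical serial order: channels
#' `acc_x, acc_y, acc_z, gyro_x, gyro_y, gyro_z`, each contributing the
#' statistics `mean, median, rms, min, max, std, range, mad` in that order.
#' Feature serials quoted elsewhere in the package are 0-based positions in
#' this vector (serial 0 = `mean_acc_x`, ..., serial 47 = `mad_gyro_z`).
#'
#' @return character vector of length 48.
#' @export
#' @examples
#' har_feature_names()[c(1, 31, 48)]
har_feature_names <- function() {
  as.vector(vapply(
    har_channel_names(),
    function(ch) paste0(har_stat_names(), "_", ch),
    character(8)
  ))
}

#' @rdname har_feature_names
#' @export
har_channel_names <- function() {
  c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")
}

#' @rdname har_feature_names
#' @export
har_stat_names <- function() {
  c("mean", "median", "rms", "min", "max", "std", "range", "mad")
}

#' Construct a labelled 6-channel signal window
#'
#' @param channels named list of 6 numeric vectors in the order of
#'   [har_channel_names()]; all samples must be finite and every channel
#'   non-empty. Channels may have different lengths (they are summarised
#'   independently).
#' @param label integer activity class id.
#' @param sample_rate sampling rate in Hz (default 100).
#' @return an object of class `signal_window`.
#' @export
signal_window <- function(channels, label, sample_rate = 100) {
  if (is.null(names(channels))) names(channels) <- har_channel_names()
  if (!identical(names(channels), har_channel_names())) {
    stop("channels must be named ", paste(har_channel_names(), collapse = ", "),
         " in that order")
  }
  for (ch in names(channels)) {
    x <- channels[[ch]]
    if (length(x) < 1L) stop("channel '", ch, "' is empty")
    if (!all(is.finite(x))) stop("channel '", ch, "' contains non-finite samples")
  }
  label <- as.integer(label)
  structure(
    list(channels = channels, label = label, sample_rate = sample_rate),
    class = "signal_window"
  )
}

#' @export
print.signal_window <- function(x, ...) {
  lens <- vapply(x$channels, length, integer(1))
  cat("<signal_window> label", x$label, "|", x$sample_rate, "Hz | samples/channel:",
      paste(lens, collapse = "/"), "\n")
  invisible(x)
}

#' Summarise one sensor channel with eight statistics
#'
#' Computes mean, median, RMS, minimum, maximum, standard deviation, range and
#' mean absolute deviation of a sample sequence. SD and MAD use the population
#' (1/n) normalisation; the median of an even-length sequence is the mean of
#' the two middle order statistics.
#'
#' @param x numeric vector of samples (length >= 1, all finite).
#' @return named numeric vector of length 8 in the order of [har_stat_names()].
#' @export
#' @examples
#' summarize_channel(c(1, 2, 3, 4))
summarize_channel <- function(x) {
  if (length(x) < 1L) stop("channel must contain at least one sample")
  if (!is.numeric(x) || !all(is.finite(x))) {
    stop("channel contains non-finite or non-numeric samples")
  }
  mu <- mean(x)
  mn <- min(x)
  mx <- max(x)
  c(
    mean   = mu,
    median = stats::median(x),
    rms    = sqrt(mean(x^2)),
    min    = mn,
    max    = mx,
    std    = sqrt(mean((x - mu)^2)),
    range  = mx - mn,
    mad    = mean(abs(x - mu))
  )
}

#' Extract the 48 statistical features of one window
#'
#' Equivalent to concatenating [summarize_channel()] over the six channels in
#' canonical order; names follow [har_feature_names()].
#'
#' @param window a [signal_window()].
#' @return named numeric vector of length 48.
#' @export
extract_features <- function(window) {
  stopifnot(inherits(window, "signal_window"))
  out <- unlist(lapply(window$channels, summarize_channel), use.names = FALSE)
  names(out) <- har_feature_names()
  out
}

#' Extract a feature table from a sequence of windows
#'
#' @param windows non-empty list of [signal_window()] objects.
#' @return a [feature_table()] with one row per window, 48 named columns and
#'   the window labels.
#' @export
extract_table <- function(windows) {
  if (length(windows) < 1L) stop("need at least one window")
  values <- t(vapply(windows, extract_features, numeric(48)))
  labels <- vapply(windows, function(w) w$label, integer(1))
  feature_table(values, labels)
}

#' Construct a feature table (n samples x named feature columns + labels)
#'
#' @param values numeric matrix, one row per sample.
#' @param labels integer class labels, one per row.
#' @param feature_names column names; defaults to `colnames(values)`, or to
#'   [har_feature_names()] for 48 unnamed columns.
#' @param informative optional integer vector of 0-based serials of columns
#'   known (by construction) to carry class signal; metadata used by the
#'   synthetic benchmark generator.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, labels, feature_names = NULL, informative = NULL) {
  values <- as.matrix(values)
  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names)) {
      if (ncol(values) == 48L) {
        feature_names <- har_feature_names()
      } else {
        feature_names <- paste0("f", seq_len(ncol(values)) - 1L)
      }
    }
  }
  stopifnot(length(feature_names) == ncol(values))
  if (nrow(values) != length(labels)) stop("one label per row required")
  if (!all(is.finite(values))) stop("feature values must be finite")
  colnames(values) <- feature_names
  structure(
    list(values = values, labels = as.integer(labels), informative = informative),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table>", nrow(x$values), "samples x", ncol(x$values), "features |",
      length(unique(x$labels)), "classes\n")
  if (!is.null(x$informative)) {
    cat("  informative serials:", paste(x$informative, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Accessors for feature tables
#' @param table a [feature_table()].
#' @return `feature_values()` the numeric matrix; `feature_labels()` the
#'   integer label vector.
#' @export
feature_values <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  table$values
}

#' @rdname feature_values
#' @export
feature_labels <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  table$labels
}

#' Subset rows of a feature table
#' @param table a [feature_table()].
#' @param i row indices.
#' @return a [feature_table()] with the selected rows.
#' @export
feature_rows <- function(table, i) {
  feature_table(table$values[i, , drop = FALSE], table$labels[i],
                feature_names = colnames(table$values),
                informative = table$informative)
}
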