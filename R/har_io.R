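# IO for the KU-HAR wide CSV dialect and the package's own artifacts.
#
# The wide layout stores one subsample per row: columns 1-300 accelerometer X,
# 301-600 acc Y, 601-900 acc Z, 901-1200 gyroscope X, 1201-1500 gyro Y,
# 1501-1800 gyro Z, column 1801 the activity class id (0-17), 1802 the usable
# channel length (trailing cells beyond it are opaque padding) and 1803 the
# subsample serial. Files without the two metadata columns (1801 columns,
# e.g. synthetic exports) are accepted; the full channel length is then used.

KUHAR_CHANNEL_SLOTS <- 300L
KUHAR_N_CLASSES <- 18L

# Full round-trippable precision for doubles (17 significant digits); keeps
# whole numbers compact.
fmt_full <- function(x) {
  out <- sprintf("%.17g", x)
  whole <- is.finite(x) & x == floor(x) & abs(x) < 1e15
  out[whole] <- sprintf("%.0f", x[whole])
  out
}

#' Read a KU-HAR wide CSV into raw window records
#'
#' @param path path to a comma-separated file with 1803 (or 1801, when the
#'   channel-length/serial metadata columns are absent) numeric fields per row.
#' @return list of `kuhar_record` objects, each holding the six channel
#'   sequences truncated to the declared channel length, plus `class_id`,
#'   `channel_length` and `serial`.
#' @export
read_kuhar_wide <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = ",")
  if (length(nf) == 0L) return(list())
  ok <- nf %in% c(1801L, 1803L)
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop("malformed row ", bad, ": expected 1803 (or 1801) fields, found ", nf[bad])
  }
  if (length(unique(nf)) != 1L) {
    stop("malformed file: rows mix ", paste(unique(nf), collapse = " and "), " fields")
  }
  dt <- data.table::fread(path, header = FALSE, sep = ",", colClasses = "numeric",
                          data.table = FALSE, showProgress = FALSE)
  m <- as.matrix(dt)
  has_meta <- ncol(m) == 1803L
  cls <- m[, 1801L]
  if (any(!is.finite(cls)) || any(cls != floor(cls)) ||
      any(cls < 0) || any(cls >= KUHAR_N_CLASSES)) {
    bad <- which(!(is.finite(cls) & cls == floor(cls) & cls >= 0 &
                     cls < KUHAR_N_CLASSES))[1L]
    stop("row ", bad, ": class_id ", cls[bad], " outside 0-", KUHAR_N_CLASSES - 1L)
  }
  lens <- if (has_meta) as.integer(m[, 1802L]) else
    rep(KUHAR_CHANNEL_SLOTS, nrow(m))
  if (any(lens < 1L | lens > KUHAR_CHANNEL_SLOTS)) {
    bad <- which(lens < 1L | lens > KUHAR_CHANNEL_SLOTS)[1L]
    stop("row ", bad, ": channel_length ", lens[bad], " outside 1-", KUHAR_CHANNEL_SLOTS)
  }
  serials <- if (has_meta) as.integer(m[, 1803L]) else seq_len(nrow(m))
  starts <- (seq_len(6L) - 1L) * KUHAR_CHANNEL_SLOTS
  lapply(seq_len(nrow(m)), function(i) {
    L <- lens[i]
    chans <- lapply(starts, function(s) unname(m[i, (s + 1L):(s + L)]))
    names(chans) <- har_channel_names()
    structure(
      c(chans, list(class_id = as.integer(cls[i]), channel_length = L,
                    serial = serials[i])),
      class = "kuhar_record"
    )
  })
}

#' Write raw window records in the KU-HAR wide layout
#'
#' Channels shorter than 300 samples are right-padded with zeros (padding is
#' opaque to the reader, which truncates at the declared channel length).
#'
#' @param records list of `kuhar_record` objects (see [read_kuhar_wide()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_kuhar_wide <- function(records, path) {
  rows <- vapply(records, function(r) {
    L <- r$channel_length
    chan <- unlist(lapply(har_channel_names(), function(ch) {
      x <- r[[ch]]
      if (length(x) != L) stop("record serial ", r$serial, ": channel '", ch,
                               "' has ", length(x), " samples, expected ", L)
      c(x, rep(0, KUHAR_CHANNEL_SLOTS - L))
    }), use.names = FALSE)
    c(chan, r$class_id, L, r$serial)
  }, numeric(6L * KUHAR_CHANNEL_SLOTS + 3L))
  lines <- apply(t(rows), 1, function(r) paste(fmt_full(r), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Convert a raw KU-HAR record to a signal window
#'
#' @param record a `kuhar_record`.
#' @param sample_rate sampling rate in Hz.
#' @return a [signal_window()].
#' @export
as_signal_window <- function(record, sample_rate = 100) {
  stopifnot(inherits(record, "kuhar_record"))
  signal_window(record[har_channel_names()], record$class_id, sample_rate)
}

#' Write / read a feature table as CSV (48 named columns + "activity")
#'
#' The header must match [har_feature_names()] followed by `activity` exactly;
#' values are written at full (round-trippable) precision and non-finite
#' values are rejected on read.
#'
#' @param table a [feature_table()] with 48 canonical columns.
#' @param path file path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a [feature_table()].
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  expect <- har_feature_names()
  if (!identical(colnames(table$values), expect)) {
    stop("schema error: feature columns must be exactly the 48 canonical names ",
         "(", expect[1], " ... ", expect[48], ")")
  }
  header <- paste(c(expect, "activity"), collapse = ",")
  body <- if (nrow(table$values)) {
    apply(cbind(table$values, table$labels), 1,
          function(r) paste(fmt_full(r), collapse = ","))
  } else {
    character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = ",", data.table = FALSE,
                          showProgress = FALSE)
  expect <- c(har_feature_names(), "activity")
  if (!identical(colnames(dt), expect)) {
    stop("schema error: header does not match the 48 canonical feature names + 'activity'")
  }
  values <- as.matrix(dt[, har_feature_names(), drop = FALSE])
  if (!all(is.finite(values))) stop("non-finite feature values in ", path)
  feature_table(values, dt[["activity"]])
}

#' Run configuration with the study's default protocol settings
#'
#' Defaults: base seed 42 with external sweep seeds 5,10,...,50; 10 folds of
#' stratified 70/30 train/test splits; optimizer population 30 for 50 epochs;
#' inner 80/20 fitness split. Optimizer-specific knobs: GJO energy decay `c1`,
#' Levy exponent/scale; WARSO weight-decay exponent `alpha`, attack
#' probability and weak-soldier relocation rule.
#'
#' @param base_seed integer master seed.
#' @param external_seeds seeds for the external cross-validation sweep.
#' @param n_folds number of independent train/test splits.
#' @param test_fraction held-out fraction per split, in (0, 1).
#' @param population optimizer population size (>= 2).
#' @param epochs optimizer iterations (>= 1).
#' @param method `"gjo"` or `"warso"`.
#' @param inner_fraction fraction of a fold's training partition held out for
#'   fitness evaluation.
#' @param c1,levy_beta,levy_scale GJO controls.
#' @param alpha,attack_probability,weak_relocation WARSO controls
#'   (`weak_relocation` one of `"median"`, `"random"`).
#' @return an object of class `run_config` (a validated list).
#' @export
run_config <- function(base_seed = 42L,
                       external_seeds = seq(5L, 50L, by = 5L),
                       n_folds = 10L,
                       test_fraction = 0.30,
                       population = 30L,
                       epochs = 50L,
                       method = c("gjo", "warso"),
                       inner_fraction = 0.20,
                       c1 = 1.5,
                       levy_beta = 1.5,
                       levy_scale = 0.01,
                       alpha = 0.5,
                       attack_probability = 0.5,
                       weak_relocation = c("median", "random")) {
  method <- match.arg(method)
  weak_relocation <- match.arg(weak_relocation)
  stopifnot(test_fraction > 0, test_fraction < 1,
            population >= 2, epochs >= 1,
            inner_fraction > 0, inner_fraction < 1,
            n_folds >= 1)
  structure(
    list(base_seed = as.integer(base_seed),
         external_seeds = as.integer(external_seeds),
         n_folds = as.integer(n_folds),
         test_fraction = test_fraction,
         population = as.integer(population),
         epochs = as.integer(epochs),
         method = method,
         inner_fraction = inner_fraction,
         c1 = c1, levy_beta = levy_beta, levy_scale = levy_scale,
         alpha = alpha, attack_probability = attack_probability,
         weak_relocation = weak_relocation),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Top-level keys override [run_config()] defaults; unknown keys are an error.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  do.call(run_config, raw)
}

#' Serialise fold outcomes and final configurations as JSON
#'
#' @param outcomes list of `fold_outcome` objects (see
#'   [run_fold_optimization()]).
#' @param config a `final_config` (see [finalize_config()]).
#' @param path file path.
#' @return the written path (writers, invisibly) or the parsed object
#'   (readers).
#' @export
write_fold_outcomes <- function(outcomes, path) {
  jsonlite::write_json(lapply(outcomes, unclass), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fold_outcomes
#' @export
read_fold_outcomes <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(raw, function(o) {
    o$fold <- as.integer(o$fold)
    o$features <- as.integer(o$features)
    structure(o, class = "fold_outcome")
  })
}

#' @rdname write_fold_outcomes
#' @export
write_final_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fold_outcomes
#' @export
read_final_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$features <- as.integer(raw$features)
  structure(raw, class = "final_config")
}
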