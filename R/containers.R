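#' Uniformly sampled skin-conductance signal
#'
#' Container for a continuous conductance recording: the sample values, the
#' sampling rate `fs` (Hz), the time of the first sample `t0` (s), and a
#' channel label (recording site, e.g. `"palm"`, `"finger"`, `"foot"`).
#'
#' @param values numeric vector of conductance samples (µS for raw data,
#'   z-units after standardisation). At least 2 samples; non-finite values are
#'   allowed only with `allow_gaps = TRUE` and are treated as recording gaps
#'   downstream (never silently filled).
#' @param fs sampling rate in Hz, > 0.
#' @param t0 time of the first sample in seconds.
#' @param label channel name.
#' @param allow_gaps permit NA/NaN samples (recording gaps). Default `FALSE`.
#'
#' @return An object of class `scr_signal`.
#' @examples
#' sig <- scr_signal(sin(seq(0, 10, by = 0.01)), fs = 100)
#' sig
#' tibble::as_tibble(sig)
#' @export
scr_signal <- function(values, fs, t0 = 0, label = "palm", allow_gaps = FALSE) {
  if (!is.numeric(values) || length(values) < 2L) {
    abort_scrlti("a signal needs a numeric vector of at least 2 samples",
                 "scrlti_bad_signal")
  }
  stopifnot_number(fs, "fs", positive = TRUE)
  stopifnot_number(t0, "t0")
  n_bad <- sum(!is.finite(values))
  if (n_bad > 0L) {
    if (!allow_gaps) {
      abort_scrlti(
        sprintf("signal contains %d non-finite sample(s) (recording gaps); load with allow_gaps = TRUE to keep them flagged", n_bad),
        "scrlti_signal_gap")
    }
    warn(sprintf("signal contains %d non-finite sample(s); epochs overlapping them will be flagged excluded", n_bad))
  }
  structure(
    list(values = as.numeric(values), fs = as.numeric(fs),
         t0 = as.numeric(t0), label = as.character(label)[1]),
    class = "scr_signal")
}

#' @export
print.scr_signal <- function(x, ...) {
  cat(sprintf("<scr_signal> %s: %d samples @ %g Hz, t = [%g, %g] s\n",
              x$label, length(x$values), x$fs, x$t0, signal_end(x)))
  invisible(x)
}

#' @export
length.scr_signal <- function(x) length(x$values)

signal_times <- function(x) x$t0 + (seq_along(x$values) - 1) / x$fs
signal_end <- function(x) x$t0 + (length(x$values) - 1) / x$fs

#' @importFrom tibble as_tibble tibble
#' @export
as_tibble.scr_signal <- function(x, ...) {
  tibble::tibble(time = signal_times(x), value = x$values, label = x$label)
}

#' Ordered event onsets
#'
#' Event onsets in seconds, strictly increasing, with optional per-event
#' condition labels. Onsets are absolute signal time (same clock as the
#' signal's `t0`).
#'
#' @param onsets numeric vector of onset times (s), strictly increasing.
#' @param labels optional character vector of condition labels, one per onset.
#' @return An object of class `scr_events`.
#' @examples
#' scr_events(c(2, 31, 65), labels = c("single", "first", "second"))
#' @export
scr_events <- function(onsets, labels = NULL) {
  if (!is.numeric(onsets) || length(onsets) < 1L || any(!is.finite(onsets))) {
    abort_scrlti("onsets must be a non-empty finite numeric vector",
                 "scrlti_bad_events")
  }
  o <- order(onsets)
  onsets <- as.numeric(onsets[o])
  if (any(diff(onsets) <= 0)) {
    abort_scrlti("event onsets must be strictly increasing (duplicates found)",
                 "scrlti_duplicate_onset")
  }
  if (!is.null(labels)) {
    if (length(labels) != length(onsets)) {
      abort_scrlti("labels must match onsets in length", "scrlti_bad_events")
    }
    labels <- as.character(labels)[o]
  }
  structure(list(onsets = onsets, labels = labels), class = "scr_events")
}

#' @export
print.scr_events <- function(x, ...) {
  cat(sprintf("<scr_events> %d onsets in [%g, %g] s%s\n",
              length(x$onsets), min(x$onsets), max(x$onsets),
              if (is.null(x$labels)) "" else ", labelled"))
  invisible(x)
}

#' @export
length.scr_events <- function(x) length(x$onsets)

#' @export
as_tibble.scr_events <- function(x, ...) {
  tibble::tibble(onset = x$onsets,
                 label = x$labels %||% rep(NA_character_, length(x$onsets)))
}

#' Matrix of extracted post-onset epochs
#'
#' `n_epochs x n_samples` matrix of signal segments following event onsets,
#' with per-epoch provenance (subject, condition, onset, excluded flag).
#' Excluded rows (recording gaps, truncated epochs) are dropped from all
#' downstream statistics.
#'
#' @param data numeric matrix, one row per epoch.
#' @param fs sampling rate of the rows in Hz.
#' @param epoch_len epoch length in seconds; `ncol(data)` must equal
#'   `round(epoch_len * fs)`.
#' @param meta data frame with one row per epoch; columns `subject`,
#'   `condition`, `onset`, `excluded` are created with defaults if absent.
#' @return An object of class `scr_epochs`.
#' @export
scr_epochs <- function(data, fs, epoch_len, meta = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) {
    abort_scrlti("epoch data must be numeric", "scrlti_bad_epochs")
  }
  stopifnot_number(fs, "fs", positive = TRUE)
  stopifnot_number(epoch_len, "epoch_len", positive = TRUE)
  n_samp <- as_count(epoch_len * fs, "epoch_len * fs")
  if (ncol(data) != n_samp) {
    abort_scrlti(sprintf(
      "epoch matrix has %d columns but epoch_len * fs = %d samples",
      ncol(data), n_samp), "scrlti_bad_epochs")
  }
  n <- nrow(data)
  if (is.null(meta)) meta <- tibble::tibble(.rows = n)
  meta <- tibble::as_tibble(meta)
  if (nrow(meta) != n) {
    abort_scrlti("meta must have one row per epoch", "scrlti_bad_epochs")
  }
  if (!"subject" %in% names(meta)) meta$subject <- rep("s1", n)
  if (!"condition" %in% names(meta)) meta$condition <- rep(NA_character_, n)
  if (!"onset" %in% names(meta)) meta$onset <- rep(NA_real_, n)
  if (!"excluded" %in% names(meta)) meta$excluded <- rep(FALSE, n)
  meta$excluded <- as.logical(meta$excluded)
  keep <- !meta$excluded
  if (any(!is.finite(data[keep, , drop = FALSE]))) {
    abort_scrlti("non-excluded epochs contain non-finite values",
                 "scrlti_bad_epochs")
  }
  structure(list(data = data, fs = as.numeric(fs),
                 epoch_len = as.numeric(epoch_len), meta = meta),
            class = "scr_epochs")
}

#' @export
print.scr_epochs <- function(x, ...) {
  cat(sprintf("<scr_epochs> %d epochs x %d samples (%g s @ %g Hz), %d excluded\n",
              nrow(x$data), ncol(x$data), x$epoch_len, x$fs,
              sum(x$meta$excluded)))
  invisible(x)
}

#' @export
dim.scr_epochs <- function(x) dim(x$data)

#' Epochs as a long tibble
#'
#' One row per (epoch, sample): columns `epoch`, `subject`, `condition`,
#' `onset`, `excluded`, `time` (s since epoch start), `value`.
#' @param x an `scr_epochs` object.
#' @param ... unused.
#' @export
as_tibble.scr_epochs <- function(x, ...) {
  n <- nrow(x$data); m <- ncol(x$data)
  tt <- (seq_len(m) - 1) / x$fs
  tibble::tibble(
    epoch = rep(seq_len(n), each = m),
    subject = rep(x$meta$subject, each = m),
    condition = rep(x$meta$condition, each = m),
    onset = rep(x$meta$onset, each = m),
    excluded = rep(x$meta$excluded, each = m),
    time = rep(tt, times = n),
    value = as.vector(t(x$data)))
}

# rows that participate in statistics
included_rows <- function(epochs) {
  epochs$data[!epochs$meta$excluded, , drop = FALSE]
}
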