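# Preprocessing chain for raw conductance recordings:
# band-pass filter -> downsample -> z-transform -> epoch + mean-centre.

#' Band-pass filter specification
#'
#' Defaults follow the standard SCR preprocessing convention: first-order
#' Butterworth sections with a 0.0159 Hz high-pass cut-off (a 10 s time
#' constant, `1/(2 * pi * 0.0159)`) and a 5 Hz low-pass cut-off, applied
#' bidirectionally (forward-backward, zero phase). `hp_cutoff = 0` disables
#' the high-pass, as used in the filter-cut-off sweep.
#'
#' @param hp_cutoff high-pass cut-off in Hz, >= 0 (0 = no high-pass).
#' @param lp_cutoff low-pass cut-off in Hz, > `hp_cutoff`.
#' @param order filter order per section (default 1).
#' @param bidirectional apply forward-backward for zero phase (default TRUE).
#' @return An object of class `scr_filter_spec`.
#' @seealso [filter_time_constant()]
#' @export
filter_spec <- function(hp_cutoff = 0.0159, lp_cutoff = 5, order = 1,
                        bidirectional = TRUE) {
  stopifnot_number(hp_cutoff, "hp_cutoff", nonneg = TRUE)
  stopifnot_number(lp_cutoff, "lp_cutoff", positive = TRUE)
  if (hp_cutoff >= lp_cutoff) {
    abort_scrlti("hp_cutoff must be below lp_cutoff", "scrlti_bad_filter")
  }
  structure(list(hp_cutoff = hp_cutoff, lp_cutoff = lp_cutoff,
                 order = as.integer(order),
                 bidirectional = isTRUE(bidirectional)),
            class = "scr_filter_spec")
}

#' Time constant of a first-order filter
#'
#' For a first-order filter with cut-off frequency `f` (Hz), the time
#' constant is `1 / (2 * pi * f)` seconds. The default high-pass cut-off of
#' 0.0159 Hz corresponds to a 10 s time constant.
#'
#' @param f cut-off frequency in Hz, > 0.
#' @return Time constant in seconds.
#' @examples
#' filter_time_constant(0.0159) # ~10 s
#' @export
filter_time_constant <- function(f) {
  stopifnot_number(f, "f", positive = TRUE)
  1 / (2 * pi * f)
}

# non-finite runs as closed time intervals [start, end]
gap_intervals <- function(sig) {
  bad <- !is.finite(sig$values)
  if (!any(bad)) return(sig$gaps %||% NULL)
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- which(r$values)
  tt <- signal_times(sig)
  new <- cbind(start = tt[starts[idx]], end = tt[ends[idx]])
  rbind(sig$gaps %||% NULL, new)
}

# fill gaps by linear interpolation so IIR filtering stays finite; the gap
# intervals remain recorded on the object and drive epoch exclusion later
fill_gaps <- function(sig) {
  bad <- !is.finite(sig$values)
  if (!any(bad)) return(sig)
  v <- sig$values
  v <- stats::approx(which(!bad), v[!bad], xout = seq_along(v),
                     method = "linear", rule = 2)$y
  sig$values <- v
  sig
}

# one forward-backward pass of a single Butterworth section, with
# odd-symmetric edge extension
filtfilt_section <- function(x, b, a, pad_len) {
  n <- length(x)
  pad_len <- min(pad_len, n - 1L)
  front <- 2 * x[1] - x[seq(pad_len + 1L, 2L)]
  back <- 2 * x[n] - x[seq(n - 1L, n - pad_len)]
  xp <- c(front, x, back)
  y <- signal::filter(signal::Arma(b = b, a = a), xp)
  y <- rev(signal::filter(signal::Arma(b = b, a = a), rev(y)))
  y[seq(pad_len + 1L, pad_len + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a cascade of a first-order (by default) high-pass and low-pass
#' Butterworth section, each run forward and backward so the net phase shift
#' is zero and the effective magnitude response is the squared single-pass
#' response. Edges are handled by odd-symmetric signal extension of length
#' `3 / cutoff` seconds (using the high-pass cut-off when present, the
#' low-pass cut-off otherwise), capped at the signal length.
#'
#' @param sig an [scr_signal].
#' @param spec an [`scr_filter_spec`][filter_spec].
#' @return A filtered [scr_signal] with the same length and sampling rate.
#' @export
bandpass <- function(sig, spec = filter_spec()) {
  stopifnot(inherits(sig, "scr_signal"), inherits(spec, "scr_filter_spec"))
  nyq <- sig$fs / 2
  if (spec$lp_cutoff >= nyq) {
    abort_scrlti(sprintf("lp_cutoff (%g Hz) must be below Nyquist (%g Hz)",
                         spec$lp_cutoff, nyq), "scrlti_bad_filter")
  }
  f_slow <- if (spec$hp_cutoff > 0) spec$hp_cutoff else spec$lp_cutoff
  warmup <- 3 * filter_time_constant(f_slow)
  dur <- (length(sig$values) - 1) / sig$fs
  if (dur < warmup) {
    abort_scrlti(sprintf(
      "signal (%g s) shorter than filter warm-up (%g s = 3 time constants)",
      dur, warmup), "scrlti_bad_filter")
  }
  gaps <- gap_intervals(sig)
  sig <- fill_gaps(sig)
  pad_len <- as.integer(round(3 / f_slow * sig$fs))
  x <- sig$values
  if (spec$hp_cutoff > 0) {
    hp <- signal::butter(spec$order, spec$hp_cutoff / nyq, type = "high")
    x <- if (spec$bidirectional) filtfilt_section(x, hp$b, hp$a, pad_len)
         else as.numeric(signal::filter(hp, x))
  }
  lp <- signal::butter(spec$order, spec$lp_cutoff / nyq, type = "low")
  x <- if (spec$bidirectional) filtfilt_section(x, lp$b, lp$a, pad_len)
       else as.numeric(signal::filter(lp, x))
  out <- scr_signal(x, fs = sig$fs, t0 = sig$t0, label = sig$label)
  out$gaps <- gaps
  out
}

#' Downsample by integer decimation
#'
#' Keeps every `fs / target_fs`-th sample starting at the first; assumes the
#' signal has already been low-pass filtered below `target_fs / 2`.
#'
#' @param sig an [scr_signal].
#' @param target_fs target sampling rate in Hz; `fs` must be an integer
#'   multiple of it.
#' @return An [scr_signal] at `target_fs`, `t0` preserved.
#' @export
downsample <- function(sig, target_fs = 10) {
  stopifnot(inherits(sig, "scr_signal"))
  stopifnot_number(target_fs, "target_fs", positive = TRUE)
  ratio <- sig$fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9) {
    abort_scrlti(sprintf("fs (%g) is not an integer multiple of target_fs (%g)",
                         sig$fs, target_fs), "scrlti_bad_argument")
  }
  ratio <- as.integer(round(ratio))
  out <- scr_signal(sig$values[seq(1L, length(sig$values), by = ratio)],
                    fs = target_fs, t0 = sig$t0, label = sig$label,
                    allow_gaps = TRUE)
  out$gaps <- sig$gaps %||% NULL
  out
}

#' z-transform a signal
#'
#' Standardises to mean 0 and standard deviation 1 using the population
#' convention (divisor n). Applied to the whole continuous series per
#' subject and channel so that evoked and baseline segments share one
#' standardisation; this absorbs between-subject amplitude differences due
#' to peripheral skin properties.
#'
#' @param sig an [scr_signal].
#' @return A standardised [scr_signal].
#' @export
ztransform <- function(sig) {
  stopifnot(inherits(sig, "scr_signal"))
  v <- sig$values
  ok <- is.finite(v)
  mu <- mean(v[ok])
  s <- sqrt(mean((v[ok] - mu)^2))
  if (!is.finite(s) || s == 0) {
    abort_scrlti("cannot z-transform a constant signal", "scrlti_bad_signal")
  }
  out <- scr_signal((v - mu) / s, fs = sig$fs, t0 = sig$t0,
                    label = sig$label, allow_gaps = TRUE)
  out$gaps <- sig$gaps %||% NULL
  out
}

#' Extract fixed-length post-onset epochs
#'
#' Cuts the `epoch_len` seconds following each event onset into one row of
#' an [scr_epochs] matrix. Sample 0 of each row is the first sample at or
#' after the onset (half-open window). Epochs that run past the end of the
#' recording or overlap a recording gap are flagged `excluded` (zero-filled,
#' never silently dropped). When `mean_centre` is set, each included row has
#' its mean removed — skin conductance level differs between trials even
#' after filtering.
#'
#' @param sig an [scr_signal].
#' @param events an [scr_events]; onsets are absolute signal time.
#' @param epoch_len epoch length in seconds (default 30).
#' @param mean_centre remove each row's mean (default TRUE).
#' @param subject subject identifier stored in the epoch metadata.
#' @return An [scr_epochs] with one row per onset, in onset order.
#' @export
extract_epochs <- function(sig, events, epoch_len = 30, mean_centre = TRUE,
                           subject = "s1") {
  stopifnot(inherits(sig, "scr_signal"), inherits(events, "scr_events"))
  n_samp <- as_count(epoch_len * sig$fs, "epoch_len * fs")
  if (any(events$onsets < sig$t0 - 1e-9)) {
    abort_scrlti("event onset precedes signal start", "scrlti_bad_events")
  }
  gaps <- gap_intervals(sig)
  n_ev <- length(events$onsets)
  data <- matrix(0, n_ev, n_samp)
  excluded <- logical(n_ev)
  n_total <- length(sig$values)
  for (i in seq_len(n_ev)) {
    start <- as.integer(ceiling((events$onsets[i] - sig$t0) * sig$fs - 1e-9)) + 1L
    idx <- seq(start, length.out = n_samp)
    if (start < 1L || max(idx) > n_total) {
      excluded[i] <- TRUE
      next
    }
    row <- sig$values[idx]
    t_lo <- events$onsets[i]
    t_hi <- t_lo + epoch_len
    in_gap <- !is.null(gaps) &&
      any(gaps[, "start"] < t_hi & gaps[, "end"] >= t_lo)
    if (any(!is.finite(row)) || in_gap) {
      excluded[i] <- TRUE
      next
    }
    data[i, ] <- if (mean_centre) row - mean(row) else row
  }
  meta <- tibble::tibble(
    subject = rep(subject, n_ev),
    condition = events$labels %||% rep(NA_character_, n_ev),
    onset = events$onsets,
    excluded = excluded)
  scr_epochs(data, fs = sig$fs, epoch_len = epoch_len, meta = meta)
}

#' Full preprocessing chain
#'
#' Applies, in order: band-pass filter (at the loaded sampling rate),
#' integer decimation to `target_fs`, whole-series z-transform, then epoch
#' extraction with per-trial mean-centring. Returns both the processed
#' continuous signal and the epoch matrix.
#'
#' @inheritParams extract_epochs
#' @param raw an [scr_signal] at its native (uniform) sampling rate.
#' @param spec an [`scr_filter_spec`][filter_spec].
#' @param target_fs analysis sampling rate in Hz (default 10).
#' @return A list with elements `signal` ([scr_signal]) and `epochs`
#'   ([scr_epochs]).
#' @export
preprocess_chain <- function(raw, events, spec = filter_spec(),
                             target_fs = 10, epoch_len = 30,
                             mean_centre = TRUE, subject = "s1") {
  sig <- bandpass(raw, spec)
  if (sig$fs != target_fs) sig <- downsample(sig, target_fs)
  sig <- ztransform(sig)
  epochs <- extract_epochs(sig, events, epoch_len = epoch_len,
                           mean_centre = mean_centre, subject = subject)
  list(signal = sig, epochs = epochs)
}
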