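# Plain-text I/O. All three data kinds share one layout: '#'-prefixed
# key=value header lines, then delimited data rows (comma or whitespace,
# auto-detected). Numbers are written with 17 significant digits so
# round-trips are lossless at double precision.

read_text_records <- function(path) {
  if (!file.exists(path)) {
    abort_scrlti(sprintf("file not found: %s", path), "scrlti_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_hdr <- startsWith(trimws(lines), "#")
  header <- list()
  for (h in trimws(sub("^\\s*#", "", lines[is_hdr]))) {
    kv <- regmatches(h, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", h))[[1]]
    if (length(kv) == 3) header[[kv[2]]] <- trimws(kv[3])
  }
  list(header = header, lines = lines[!is_hdr])
}

split_fields <- function(lines) {
  delim <- if (any(grepl(",", lines, fixed = TRUE))) "," else "[[:space:]]+"
  lapply(strsplit(trimws(lines), delim), trimws)
}

header_num <- function(header, key) {
  if (is.null(header[[key]])) return(NULL)
  as.numeric(header[[key]])
}

#' Read a conductance signal from delimited text
#'
#' Accepts either two columns (time, value) or a single value column plus a
#' stated sampling rate (`fs_override` or an `# fs=` header line). Header
#' lines `# fs=`, `# t0=`, `# label=` are honoured. Non-uniform timestamps
#' are linearly interpolated onto a uniform grid at the stated rate; this is
#' recorded in the returned object's `resampled` field, and a warning is
#' emitted when the slowest observed input rate falls below 10 Hz (risk of
#' aliasing in the original pulse-coded acquisition).
#'
#' @param path file path.
#' @param fs_override sampling rate in Hz; overrides any header value and is
#'   required for single-column files without an `fs` header.
#' @return An [scr_signal] object.
#' @export
read_signal <- function(path, fs_override = NULL) {
  rec <- read_text_records(path)
  rows <- split_fields(rec$lines)
  if (length(rows) < 2L) {
    abort_scrlti("signal file needs at least 2 samples", "scrlti_io_error")
  }
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L || !ncols %in% c(1L, 2L)) {
    abort_scrlti("signal file must have 1 or 2 columns throughout",
                 "scrlti_io_error")
  }
  fs_stated <- fs_override %||% header_num(rec$header, "fs")
  t0 <- header_num(rec$header, "t0") %||% 0
  label <- rec$header$label %||% "palm"
  num <- function(i) {
    v <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", i)))
    if (anyNA(v)) {
      abort_scrlti("unparsable numeric field in signal file", "scrlti_io_error")
    }
    v
  }
  if (ncols == 1L) {
    if (is.null(fs_stated)) {
      abort_scrlti("single-column signal file needs fs (header or fs_override)",
                   "scrlti_io_error")
    }
    return(scr_signal(num(1), fs = fs_stated, t0 = t0, label = label))
  }
  tt <- num(1); vv <- num(2)
  dt <- diff(tt)
  if (any(dt <= 0)) {
    abort_scrlti("timestamps must be strictly increasing", "scrlti_io_error")
  }
  uniform <- max(abs(dt - dt[1])) <= 1e-6 * dt[1]
  if (uniform) {
    fs <- 1 / dt[1]
    if (!is.null(fs_stated) && abs(fs_stated - fs) > 1e-6 * fs) {
      # caller asked for a different grid: resample even though input uniform
      uniform <- FALSE
    } else {
      return(scr_signal(vv, fs = fs, t0 = tt[1], label = label))
    }
  }
  if (is.null(fs_stated)) {
    abort_scrlti("non-uniform timestamps: state the target rate via fs_override or an fs header",
                 "scrlti_io_error")
  }
  min_rate <- 1 / max(dt)
  if (min_rate < 10) {
    warn(sprintf("slowest observed input rate is %.2f Hz (< 10 Hz); aliasing may be present",
                 min_rate))
  }
  n_grid <- floor((tt[length(tt)] - tt[1]) * fs_stated + 1e-9) + 1L
  grid <- tt[1] + (seq_len(n_grid) - 1) / fs_stated
  out <- stats::approx(tt, vv, xout = grid, method = "linear", rule = 2)$y
  sig <- scr_signal(out, fs = fs_stated, t0 = tt[1], label = label)
  sig$resampled <- TRUE
  sig
}

#' Write a signal to delimited text
#'
#' Writes `# fs=`, `# t0=`, `# label=` headers followed by one sample value
#' per line. [read_signal] on the result reproduces the object exactly.
#'
#' @param x an [scr_signal].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(x, path) {
  stopifnot(inherits(x, "scr_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%s", fmt_num(x$fs)),
               sprintf("# t0=%s", fmt_num(x$t0)),
               sprintf("# label=%s", x$label),
               fmt_num(x$values)), con)
  invisible(path)
}

#' Read event onsets from text
#'
#' One onset time (seconds) per line, with an optional second field giving a
#' condition label. Lines starting with `#` are ignored. Duplicate onsets are
#' rejected.
#'
#' @param path file path.
#' @return An [scr_events] object.
#' @export
read_events <- function(path) {
  rec <- read_text_records(path)
  rows <- split_fields(rec$lines)
  if (length(rows) == 0L) {
    abort_scrlti("event file contains no onsets", "scrlti_io_error")
  }
  onsets <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 1)))
  if (anyNA(onsets)) {
    abort_scrlti("unparsable onset line in event file", "scrlti_io_error")
  }
  labels <- NULL
  if (any(lengths(rows) > 1L)) {
    labels <- vapply(rows, function(r) if (length(r) > 1L) r[[2]] else NA_character_, "")
  }
  if (anyDuplicated(onsets)) {
    abort_scrlti("duplicate event onset in file", "scrlti_duplicate_onset")
  }
  scr_events(onsets, labels)
}

#' Write event onsets to text
#' @param x an [scr_events].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(x, path) {
  stopifnot(inherits(x, "scr_events"))
  lines <- fmt_num(x$onsets)
  if (!is.null(x$labels)) lines <- paste(lines, x$labels)
  writeLines(lines, path)
  invisible(path)
}

#' Read and write epoch matrices
#'
#' Epoch files carry `# fs=`, `# epoch_len=`, `# n_samples=` headers and one
#' tab-delimited row per epoch: `subject condition onset excluded v1 ... vn`.
#' The round trip `read_epochs(write_epochs(x))` is lossless to double
#' precision on the data and exact on the metadata. Writing a matrix with
#' non-finite values is refused.
#'
#' @param x an [scr_epochs].
#' @param path file path.
#' @return `write_epochs`: `path`, invisibly. `read_epochs`: an [scr_epochs].
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "scr_epochs"))
  if (nrow(x$data) > 0 && any(!is.finite(x$data))) {
    abort_scrlti("refusing to write epochs containing non-finite values",
                 "scrlti_io_error")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%s", fmt_num(x$fs)),
               sprintf("# epoch_len=%s", fmt_num(x$epoch_len)),
               sprintf("# n_samples=%d", ncol(x$data))), con)
  if (nrow(x$data) > 0) {
    rows <- vapply(seq_len(nrow(x$data)), function(i) {
      paste(c(x$meta$subject[i],
              x$meta$condition[i] %||% NA_character_,
              fmt_num(x$meta$onset[i]),
              as.integer(x$meta$excluded[i]),
              fmt_num(x$data[i, ])), collapse = "\t")
    }, "")
    writeLines(rows, con)
  }
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  rec <- read_text_records(path)
  fs <- header_num(rec$header, "fs")
  epoch_len <- header_num(rec$header, "epoch_len")
  n_samples <- header_num(rec$header, "n_samples")
  if (is.null(fs) || is.null(epoch_len) || is.null(n_samples)) {
    abort_scrlti("epoch file must carry fs, epoch_len and n_samples headers",
                 "scrlti_io_error")
  }
  rows <- strsplit(rec$lines, "\t", fixed = TRUE)
  n <- length(rows)
  if (n == 0L) {
    return(scr_epochs(matrix(numeric(0), 0, n_samples), fs, epoch_len))
  }
  if (any(lengths(rows) != n_samples + 4L)) {
    abort_scrlti("epoch row length does not match n_samples header",
                 "scrlti_io_error")
  }
  meta <- tibble::tibble(
    subject = vapply(rows, `[[`, "", 1),
    condition = vapply(rows, `[[`, "", 2),
    onset = as.numeric(vapply(rows, `[[`, "", 3)),
    excluded = as.integer(vapply(rows, `[[`, "", 4)) > 0L)
  meta$condition[meta$condition == "NA"] <- NA_character_
  data <- t(vapply(rows, function(r) as.numeric(r[-(1:4)]),
                   numeric(n_samples)))
  scr_epochs(data, fs, epoch_len, meta)
}
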