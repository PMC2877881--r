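# Convolution GLM: each event contributes a stick function (unit impulse at
# its onset sample) convolved with each basis function; amplitudes are
# estimated by ordinary least squares.

#' Build a convolution design matrix
#'
#' For each event (or each event label when `per_event = FALSE`), every
#' basis row is convolved with a unit-height impulse at the onset sample
#' (the first sample at or after the onset), truncated at `n_samples`; a
#' constant column is appended last.
#'
#' @param events an [scr_events]; onsets in seconds relative to sample 0 of
#'   the series being modelled, all within `[0, n_samples / fs)`.
#' @param basis an [`scr_basis`][build_basis] sampled at `fs`.
#' @param n_samples length of the modelled series.
#' @param fs sampling rate (Hz); must match `basis$fs`.
#' @param per_event one regressor set per event (TRUE, the per-trial
#'   estimation path) or per event label (FALSE, condition-level design).
#' @return An object of class `scr_design`: `X` (n_samples x n_regressors),
#'   `names`, `fs`, and an `event_map` tibble linking columns to events and
#'   basis functions.
#' @export
build_design <- function(events, basis, n_samples, fs, per_event = TRUE) {
  stopifnot(inherits(events, "scr_events"), inherits(basis, "scr_basis"))
  n_samples <- as_count(n_samples, "n_samples")
  if (abs(basis$fs - fs) > 1e-9) {
    abort_scrlti("basis sampling rate does not match fs", "scrlti_bad_argument")
  }
  if (any(events$onsets < 0 | events$onsets >= n_samples / fs)) {
    abort_scrlti("event onset outside the modelled series", "scrlti_bad_events")
  }
  if (per_event) {
    groups <- as.list(seq_along(events$onsets))
    gnames <- sprintf("ev%d", seq_along(events$onsets))
  } else {
    labs <- events$labels %||% rep("event", length(events$onsets))
    gnames <- unique(labs)
    groups <- lapply(gnames, function(g) which(labs == g))
  }
  nb <- nrow(basis$matrix)
  cols <- list()
  map <- list()
  nbs <- ncol(basis$matrix)
  for (gi in seq_along(groups)) {
    idx <- as.integer(ceiling(events$onsets[groups[[gi]]] * fs - 1e-9)) + 1L
    for (bi in seq_len(nb)) {
      # convolution of the sparse stick train with the basis row, by direct
      # placement of truncated shifted copies (exact, no FFT roundoff)
      col <- numeric(n_samples)
      for (i0 in idx) {
        j <- seq(i0, min(n_samples, i0 + nbs - 1L))
        col[j] <- col[j] + basis$matrix[bi, seq_along(j)]
      }
      nm <- paste(gnames[gi], basis$names[bi], sep = "_")
      cols[[nm]] <- col
      map[[length(map) + 1L]] <- tibble::tibble(
        column = nm, group = gnames[gi], basis = basis$names[bi],
        onsets = list(events$onsets[groups[[gi]]]))
    }
  }
  X <- cbind(do.call(cbind, cols), constant = 1)
  structure(list(X = X, names = colnames(X), fs = fs,
                 event_map = dplyr::bind_rows(map)),
            class = "scr_design")
}

#' @export
print.scr_design <- function(x, ...) {
  cat(sprintf("<scr_design> %d samples x %d regressors (%s)\n",
              nrow(x$X), ncol(x$X), paste(x$names, collapse = ", ")))
  invisible(x)
}

#' Ordinary least squares fit of a convolution design
#'
#' Rank-revealing (QR) least squares of a signal or epoch row on a
#' [build_design] matrix. Residuals are orthogonal to every design column
#' and `fitted + residuals` reproduces the data exactly.
#'
#' @param y numeric vector, or an [scr_signal] (its values are used).
#' @param design an `scr_design` with `nrow(X) == length(y)`.
#' @return An object of class `scr_glm`: `beta` (named), `se` (i.i.d.-noise
#'   standard errors), `fitted`, `residuals`, `residual_var` (residual
#'   fraction of the centred total variance), `explained` (its complement),
#'   `df_residual`, `design`.
#' @export
fit_glm <- function(y, design) {
  stopifnot(inherits(design, "scr_design"))
  if (inherits(y, "scr_signal")) y <- y$values
  X <- design$X
  if (length(y) != nrow(X)) {
    abort_scrlti("length(y) does not match the design", "scrlti_bad_argument")
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    abort_scrlti(
      "design is rank deficient (collinear regressors, e.g. coincident events)",
      "scrlti_rank_deficient")
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  dfr <- length(y) - ncol(X)
  sigma2 <- if (dfr > 0) rss / dfr else NA_real_
  XtXinv <- chol2inv(qr.R(qrx))
  se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
  names(se) <- names(beta)
  structure(list(beta = beta, se = se, fitted = fitted, residuals = res,
                 residual_var = if (tss > 0) rss / tss else NA_real_,
                 explained = if (tss > 0) 1 - rss / tss else NA_real_,
                 df_residual = dfr, design = design),
            class = "scr_glm")
}

#' @export
print.scr_glm <- function(x, ...) {
  cat(sprintf("<scr_glm> %d regressors, explained variance %.1f%%\n",
              length(x$beta), 100 * x$explained))
  print(round(x$beta, 4))
  invisible(x)
}

#' Repetition-by-ISI linearity analysis
#'
#' Per subject, estimates a response function as the first principal
#' component of the single-stimulus epochs (peak-normalised), then fits
#' every double-stimulus epoch with a design holding that response function
#' at the first onset (epoch time 0), at the second onset (the trial's ISI),
#' and a constant. Aggregates the resulting first/second amplitudes per
#' repetition x ISI cell, computes within-subject regression slopes of the
#' second on the first amplitude (per ISI and pooled), and tests the subject
#' slopes against zero with one-sample t-tests. Under a linear time-invariant
#' system with ISI-independent repetition suppression, the second/first
#' amplitude ratio is constant across ISIs and the ratio-on-ISI trend is
#' zero; an amplitude-dependent refractory period would show up as negative
#' slopes.
#'
#' @param single an [scr_epochs] of single-stimulus trials with
#'   `meta$subject`; at least 2 per subject.
#' @param double an [scr_epochs] of double-stimulus trials with
#'   `meta$subject` and `meta$isi` (seconds between the two onsets); epochs
#'   start at the first onset and must be long enough to contain the second
#'   response (`epoch_len >= single$epoch_len + max(isi)` recommended).
#' @return An object of class `scr_linearity`: tibbles `trials` (per-trial
#'   beta1/beta2), `amplitudes` (subject x ISI x repetition means),
#'   `ratios` (per-ISI grand mean-amplitude ratios and the ratio-on-ISI
#'   trend slope), `slopes` (within-subject regression slopes), and
#'   `slope_tests` (one-sample t per ISI and pooled).
#' @export
linearity_analysis <- function(single, double) {
  stopifnot(inherits(single, "scr_epochs"), inherits(double, "scr_epochs"))
  if (!"isi" %in% names(double$meta)) {
    abort_scrlti("double-trial epochs need an `isi` metadata column",
                 "scrlti_bad_epochs")
  }
  if (abs(single$fs - double$fs) > 1e-9) {
    abort_scrlti("single and double epochs must share one sampling rate",
                 "scrlti_bad_epochs")
  }
  fs <- single$fs
  subjects <- unique(double$meta$subject[!double$meta$excluded])
  trials <- purrr::map_dfr(subjects, function(sj) {
    s_idx <- single$meta$subject == sj & !single$meta$excluded
    if (sum(s_idx) < 2L) {
      abort_scrlti(sprintf("subject %s has < 2 single trials", sj),
                   "scrlti_bad_epochs")
    }
    s_ep <- scr_epochs(single$data[s_idx, , drop = FALSE], fs,
                       single$epoch_len, single$meta[s_idx, ])
    rf <- epoch_pca(s_ep, k = 1)$components[1, ]
    if (max(abs(rf)) == 0) {
      abort_scrlti(sprintf("subject %s: degenerate (all-zero) response function", sj),
                   "scrlti_degenerate_rf")
    }
    rf <- rf / max(rf)
    rf_basis <- structure(
      list(matrix = matrix(rf, 1), names = "rf", fs = fs, params = NULL,
           normalisation = "subject PC1, peak-normalised",
           orthogonalised = FALSE),
      class = "scr_basis")
    d_idx <- which(double$meta$subject == sj & !double$meta$excluded)
    purrr::map_dfr(d_idx, function(i) {
      isi <- double$meta$isi[i]
      des <- build_design(scr_events(c(0, isi)), rf_basis,
                          n_samples = ncol(double$data), fs = fs)
      fit <- fit_glm(double$data[i, ], des)
      tibble::tibble(subject = sj, isi = isi,
                     beta1 = unname(fit$beta[1]), beta2 = unname(fit$beta[2]),
                     explained = fit$explained)
    })
  })
  amplitudes <- trials |>
    tidyr::pivot_longer(c("beta1", "beta2"), names_to = "repetition",
                        values_to = "beta") |>
    dplyr::mutate(repetition = ifelse(.data$repetition == "beta1",
                                      "first", "second")) |>
    dplyr::group_by(.data$subject, .data$isi, .data$repetition) |>
    dplyr::summarise(mean_beta = mean(.data$beta), n_trials = dplyr::n(),
                     .groups = "drop")
  ratios <- trials |>
    dplyr::group_by(.data$isi) |>
    dplyr::summarise(mean_beta1 = mean(.data$beta1),
                     mean_beta2 = mean(.data$beta2),
                     ratio = mean(.data$beta2) / mean(.data$beta1),
                     .groups = "drop")
  trend <- unname(coef(lm(ratio ~ isi, data = ratios))[2])
  slope_of <- function(d) {
    if (nrow(d) < 2L || sd(d$beta1) == 0) return(NA_real_)
    unname(coef(lm(beta2 ~ beta1, data = d))[2])
  }
  slopes <- dplyr::bind_rows(
    trials |> dplyr::group_by(.data$subject, .data$isi) |>
      dplyr::group_modify(~ tibble::tibble(slope = slope_of(.x))) |>
      dplyr::ungroup(),
    trials |> dplyr::group_by(.data$subject) |>
      dplyr::group_modify(~ tibble::tibble(slope = slope_of(.x))) |>
      dplyr::ungroup() |> dplyr::mutate(isi = NA_real_))
  ttest <- function(s) {
    s <- s[is.finite(s)]
    if (length(s) < 2L || sd(s) <= 1e-10 * (abs(mean(s)) + 1)) {
      return(tibble::tibble(mean_slope = mean(s), t = NA_real_,
                            df = length(s) - 1, p = NA_real_))
    }
    tt <- t.test(s)
    tibble::tibble(mean_slope = unname(tt$estimate), t = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value)
  }
  slope_tests <- slopes |>
    dplyr::mutate(scope = ifelse(is.na(.data$isi), "pooled",
                                 as.character(.data$isi))) |>
    dplyr::group_by(.data$scope) |>
    dplyr::group_modify(~ ttest(.x$slope)) |>
    dplyr::ungroup()
  structure(list(trials = trials, amplitudes = amplitudes, ratios = ratios,
                 ratio_isi_trend = trend, slopes = slopes,
                 slope_tests = slope_tests),
            class = "scr_linearity")
}

#' @export
print.scr_linearity <- function(x, ...) {
  cat("<scr_linearity>\n  second/first amplitude ratio by ISI:\n")
  for (i in seq_len(nrow(x$ratios))) {
    cat(sprintf("    ISI %g s: %.3f\n", x$ratios$isi[i], x$ratios$ratio[i]))
  }
  cat(sprintf("  ratio-on-ISI trend: %.4g per s\n", x$ratio_isi_trend))
  pooled <- x$slope_tests[x$slope_tests$scope == "pooled", ]
  if (nrow(pooled) == 1 && is.finite(pooled$t)) {
    cat(sprintf("  pooled within-subject slope: %.3f (t = %.2f, df = %g, p = %.3g)\n",
                pooled$mean_slope, pooled$t, pooled$df, pooled$p))
  }
  invisible(x)
}
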