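# Empirical response-function estimation. The first principal component of
# the (row-mean-centred, NOT column-centred) epoch matrix is the response
# template: with column centring a shape common to all epochs would vanish
# into the removed mean, so the decomposition is of the epochs' second
# moment about zero across rows.

#' Principal component analysis of event-related epochs
#'
#' Eigen-analysis of the epochs' second-moment matrix across rows, without
#' column centring, computed via the singular value decomposition of the
#' epoch matrix. The first component is the response function explaining the
#' maximum variance; its explained fraction is the within-subject
#' time-invariance summary. Excluded epochs are dropped.
#'
#' @param epochs an [scr_epochs] with at least 2 non-excluded rows; rows are
#'   expected to be mean-centred already.
#' @param k number of components to return (default 3, capped at the rank
#'   bound `min(n_epochs, n_samples)`).
#' @return An object of class `scr_pca`: `components` (k x n_samples,
#'   orthonormal rows; component 1 oriented so its largest-magnitude sample
#'   is positive), `eigenvalues` (descending), `explained_fraction`,
#'   `n_epochs`, `fs`.
#' @export
epoch_pca <- function(epochs, k = 3) {
  stopifnot(inherits(epochs, "scr_epochs"))
  X <- included_rows(epochs)
  if (nrow(X) < 2L) {
    abort_scrlti("epoch_pca needs at least 2 non-excluded epochs",
                 "scrlti_bad_epochs")
  }
  if (k > min(dim(X))) {
    abort_scrlti(sprintf("k (%d) exceeds min(n_epochs, n_samples) = %d",
                         k, min(dim(X))), "scrlti_bad_argument")
  }
  total <- sum(X^2)
  if (total == 0) {
    abort_scrlti("epoch matrix is all zero", "scrlti_bad_epochs")
  }
  sv <- svd(X, nu = 0, nv = k)
  comps <- t(sv$v)
  for (i in seq_len(nrow(comps))) { # orient: largest-magnitude sample positive
    j <- which.max(abs(comps[i, ]))
    if (comps[i, j] < 0) comps[i, ] <- -comps[i, ]
  }
  ev <- sv$d[seq_len(k)]^2 / nrow(X)
  structure(list(components = comps,
                 eigenvalues = ev,
                 explained_fraction = sv$d[seq_len(k)]^2 / total,
                 n_epochs = nrow(X), fs = epochs$fs),
            class = "scr_pca")
}

#' @export
print.scr_pca <- function(x, ...) {
  cat(sprintf("<scr_pca> %d component(s) from %d epochs; explained: %s\n",
              nrow(x$components), x$n_epochs,
              paste(sprintf("%.1f%%", 100 * x$explained_fraction),
                    collapse = ", ")))
  invisible(x)
}

#' Within/between-subject variance partition
#'
#' Decomposes the pooled epoch variance into three components: variance
#' explained by one common response function (the pooled first principal
#' component), additional variance explained by subject-specific response
#' functions (between-subjects shape variance), and residual variance.
#' Within-subject explained fractions are combined weighted by each
#' subject's total epoch variance, so the three components decompose the
#' pooled variance exactly and sum to 1.
#'
#' @param per_subject_epochs list of [scr_epochs], one per subject, each
#'   with at least 2 non-excluded epochs and mean-centred rows.
#' @return An object of class `scr_variance_partition` with fields `common`,
#'   `between_subjects`, `residual`, and a `per_subject` tibble (subject,
#'   explained fraction, epoch count, total variance weight).
#' @export
variance_partition <- function(per_subject_epochs) {
  if (!is.list(per_subject_epochs) || length(per_subject_epochs) < 2L) {
    abort_scrlti("variance_partition needs a list of >= 2 subjects' epochs",
                 "scrlti_bad_argument")
  }
  per <- purrr::map(per_subject_epochs, function(ep) {
    p <- epoch_pca(ep, k = 1)
    X <- included_rows(ep)
    tibble::tibble(subject = ep$meta$subject[!ep$meta$excluded][1],
                   explained = p$explained_fraction[1],
                   n_epochs = p$n_epochs,
                   weight = sum(X^2))
  })
  per <- dplyr::bind_rows(per)
  pooled_data <- do.call(rbind, purrr::map(per_subject_epochs, included_rows))
  fs <- per_subject_epochs[[1]]$fs
  el <- per_subject_epochs[[1]]$epoch_len
  pooled <- epoch_pca(scr_epochs(pooled_data, fs, el), k = 1)
  common <- pooled$explained_fraction[1]
  within <- sum(per$weight * per$explained) / sum(per$weight)
  structure(list(common = common,
                 between_subjects = within - common,
                 residual = 1 - within,
                 per_subject = per,
                 pooled_component = pooled$components[1, ],
                 fs = fs),
            class = "scr_variance_partition")
}

#' @export
print.scr_variance_partition <- function(x, ...) {
  cat(sprintf(
    "<scr_variance_partition> common %.1f%% | between-subjects %.1f%% | residual %.1f%% (%d subjects)\n",
    100 * x$common, 100 * x$between_subjects, 100 * x$residual,
    nrow(x$per_subject)))
  invisible(x)
}

#' Baseline-to-evoked variance ratio
#'
#' Total variance of baseline epochs divided by total variance of evoked
#' epochs, each computed as the mean squared value of the row-mean-centred
#' epochs pooled over epochs and samples. Both epoch sets must come from the
#' same z-transformed series (a shared standardisation), otherwise the ratio
#' is meaningless. A ratio above the residual fraction of the evoked
#' time-invariance decomposition indicates that spontaneous fluctuations are
#' a sufficient explanation of the model residuals.
#'
#' @param evoked,baseline [scr_epochs] sharing one standardisation.
#' @return A single fraction.
#' @export
baseline_ratio <- function(evoked, baseline) {
  stopifnot(inherits(evoked, "scr_epochs"), inherits(baseline, "scr_epochs"))
  ms <- function(ep) {
    X <- included_rows(ep)
    X <- X - rowMeans(X)
    sum(X^2) / length(X)
  }
  v_ev <- ms(evoked)
  if (v_ev == 0) {
    abort_scrlti("evoked epochs have zero variance", "scrlti_bad_epochs")
  }
  ms(baseline) / v_ev
}

#' High-pass cut-off sweep
#'
#' Reruns the preprocessing chain and epoch PCA for each high-pass cut-off
#' (0 = no high-pass) and reports the first-component explained fraction,
#' quantifying how the choice of high-pass filter affects the apparent
#' response.
#'
#' @inheritParams preprocess_chain
#' @param cutoffs high-pass cut-offs in Hz (default 0 to 0.025 in 0.005
#'   steps); all must be below the low-pass cut-off.
#' @return A tibble with columns `cutoff` and `explained`.
#' @export
filter_sweep <- function(raw, events, cutoffs = seq(0, 0.025, by = 0.005),
                         spec = filter_spec(), target_fs = 10,
                         epoch_len = 30) {
  if (any(cutoffs >= spec$lp_cutoff)) {
    abort_scrlti("all sweep cutoffs must be below the low-pass cut-off",
                 "scrlti_bad_filter")
  }
  purrr::map_dfr(cutoffs, function(hp) {
    sp <- filter_spec(hp_cutoff = hp, lp_cutoff = spec$lp_cutoff,
                      order = spec$order,
                      bidirectional = spec$bidirectional)
    pp <- preprocess_chain(raw, events, spec = sp, target_fs = target_fs,
                           epoch_len = epoch_len)
    tibble::tibble(cutoff = hp,
                   explained = epoch_pca(pp$epochs, k = 1)$explained_fraction[1])
  })
}

#' Time-lagged correlation between recording sites
#'
#' Squared Pearson correlation between `a(t)` and `b(t + lag)` over the
#' overlapping segment, for every lag on the sample grid in
#' `[-max_lag, max_lag]`. A positive best lag means `b` trails `a`
#' (e.g. foot recordings trail palmar ones); ties in the maximum are broken
#' toward the smaller absolute lag.
#'
#' @param a,b [scr_signal] objects with equal sampling rates.
#' @param max_lag largest lag magnitude to scan, in seconds; the overlap
#'   must be at least 10 times this.
#' @return An object of class `scr_lagcorr`: tibble `by_lag` (`lag`, `r2`),
#'   plus `best_lag` (s) and `best_r2`.
#' @export
lagged_correlation <- function(a, b, max_lag = 5) {
  stopifnot(inherits(a, "scr_signal"), inherits(b, "scr_signal"))
  if (abs(a$fs - b$fs) > 1e-9) {
    abort_scrlti("signals must share one sampling rate", "scrlti_bad_argument")
  }
  if (sd(a$values) == 0 || sd(b$values) == 0) {
    abort_scrlti("lagged correlation of a constant signal is undefined",
                 "scrlti_bad_signal")
  }
  fs <- a$fs
  max_k <- as.integer(floor(max_lag * fs + 1e-9))
  n <- min(length(a$values), length(b$values))
  if (n < 10 * max_k) {
    abort_scrlti("insufficient overlap: need at least 10 x max_lag samples",
                 "scrlti_bad_argument")
  }
  ks <- seq(-max_k, max_k)
  r2 <- vapply(ks, function(k) {
    ia <- seq(max(1, 1 - k), min(n, n - k))
    cor(a$values[ia], b$values[ia + k])^2
  }, numeric(1))
  # ties toward smaller |lag|: scan in order of increasing |k|
  ord <- order(abs(ks), ks)
  best <- ord[which.max(r2[ord])]
  structure(list(by_lag = tibble::tibble(lag = ks / fs, r2 = r2),
                 best_lag = ks[best] / fs, best_r2 = r2[best],
                 fs = fs, labels = c(a$label, b$label)),
            class = "scr_lagcorr")
}

#' @export
print.scr_lagcorr <- function(x, ...) {
  cat(sprintf("<scr_lagcorr> %s vs %s: best lag %.3g s, shared variance %.1f%%\n",
              x$labels[1], x$labels[2], x$best_lag, 100 * x$best_r2))
  invisible(x)
}
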