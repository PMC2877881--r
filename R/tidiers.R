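# broom-style tidiers for the package's result objects

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an epoch PCA
#'
#' One row per (component, sample): columns `component`, `time`, `value`,
#' plus the component's `explained` fraction.
#' @param x an `scr_pca` object.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.scr_pca <- function(x, ...) {
  k <- nrow(x$components); m <- ncol(x$components)
  tibble::tibble(
    component = rep(seq_len(k), each = m),
    time = rep((seq_len(m) - 1) / x$fs, times = k),
    value = as.vector(t(x$components)),
    explained = rep(x$explained_fraction, each = m))
}

#' @rdname tidy.scr_pca
#' @export
glance.scr_pca <- function(x, ...) {
  tibble::tibble(n_epochs = x$n_epochs,
                 n_components = nrow(x$components),
                 explained_1 = x$explained_fraction[1],
                 explained_total = sum(x$explained_fraction))
}

#' Tidy a variance partition
#'
#' `tidy()` returns the three pooled variance components; `glance()` a
#' one-row summary with subject counts.
#' @param x an `scr_variance_partition`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.scr_variance_partition <- function(x, ...) {
  tibble::tibble(
    component = c("common", "between_subjects", "residual"),
    fraction = c(x$common, x$between_subjects, x$residual))
}

#' @rdname tidy.scr_variance_partition
#' @export
glance.scr_variance_partition <- function(x, ...) {
  tibble::tibble(n_subjects = nrow(x$per_subject),
                 n_epochs = sum(x$per_subject$n_epochs),
                 common = x$common, between_subjects = x$between_subjects,
                 residual = x$residual,
                 mean_within = x$common + x$between_subjects)
}

#' Tidy a GLM fit
#'
#' `tidy()`: one row per regressor with `term`, `estimate`, `std.error`,
#' `statistic`. `glance()`: explained variance and residual df.
#' @param x an `scr_glm`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.scr_glm <- function(x, ...) {
  tibble::tibble(term = names(x$beta),
                 estimate = unname(x$beta),
                 std.error = unname(x$se),
                 statistic = unname(x$beta / x$se))
}

#' @rdname tidy.scr_glm
#' @export
glance.scr_glm <- function(x, ...) {
  tibble::tibble(r.squared = x$explained,
                 residual_var = x$residual_var,
                 df.residual = x$df_residual,
                 n_regressors = length(x$beta))
}

#' Tidy a lagged cross-site correlation
#'
#' `tidy()`: the full lag grid with shared-variance fractions; `glance()`:
#' the best lag and its shared variance.
#' @param x an `scr_lagcorr`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.scr_lagcorr <- function(x, ...) x$by_lag

#' @rdname tidy.scr_lagcorr
#' @export
glance.scr_lagcorr <- function(x, ...) {
  tibble::tibble(best_lag = x$best_lag, best_r2 = x$best_r2,
                 a = x$labels[1], b = x$labels[2])
}

#' Tidy a linearity analysis
#'
#' `tidy()`: the subject x ISI x repetition mean-amplitude table;
#' `glance()`: per-ISI amplitude ratios, the ratio-on-ISI trend, and the
#' pooled within-subject slope test.
#' @param x an `scr_linearity`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.scr_linearity <- function(x, ...) x$amplitudes

#' @rdname tidy.scr_linearity
#' @export
glance.scr_linearity <- function(x, ...) {
  pooled <- x$slope_tests[x$slope_tests$scope == "pooled", ]
  out <- tibble::tibble(ratio_isi_trend = x$ratio_isi_trend,
                        pooled_slope = pooled$mean_slope,
                        pooled_slope_t = pooled$t,
                        pooled_slope_p = pooled$p)
  for (i in seq_len(nrow(x$ratios))) {
    out[[sprintf("ratio_isi%g", x$ratios$isi[i])]] <- x$ratios$ratio[i]
  }
  out
}
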