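# ggplot2 autoplot methods for quick diagnostics

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_point
#'   geom_vline labs facet_wrap position_dodge
#' @export
ggplot2::autoplot

#' Plot a signal trace
#' @param object an `scr_signal`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.scr_signal <- function(object, ...) {
  ggplot(tibble::as_tibble(object), aes(x = .data$time, y = .data$value)) +
    geom_line() +
    labs(x = "time (s)", y = "conductance",
         title = sprintf("%s (%g Hz)", object$label, object$fs))
}

#' Plot a basis set
#' @param object an `scr_basis`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.scr_basis <- function(object, ...) {
  ggplot(tibble::as_tibble(object),
         aes(x = .data$time, y = .data$value, colour = .data$name)) +
    geom_line() +
    labs(x = "time (s)", y = "basis value", colour = NULL)
}

#' Plot estimated response functions
#' @param object an `scr_pca`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.scr_pca <- function(object, ...) {
  d <- tidy(object)
  d$component <- sprintf("PC%d (%.1f%%)", d$component, 100 * d$explained)
  ggplot(d, aes(x = .data$time, y = .data$value, colour = .data$component)) +
    geom_line() +
    labs(x = "time (s)", y = "component value", colour = NULL)
}

#' Plot a variance partition
#' @param object an `scr_variance_partition`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.scr_variance_partition <- function(object, ...) {
  d <- tidy(object)
  d$component <- factor(d$component,
                        levels = c("common", "between_subjects", "residual"))
  ggplot(d, aes(x = "pooled", y = .data$fraction, fill = .data$component)) +
    geom_col() +
    labs(x = NULL, y = "fraction of pooled variance", fill = NULL)
}

#' Plot shared variance against lag
#' @param object an `scr_lagcorr`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.scr_lagcorr <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$lag, y = .data$r2)) +
    geom_line() +
    geom_vline(xintercept = object$best_lag, linetype = "dashed") +
    labs(x = "lag (s)", y = expression(r^2),
         title = sprintf("%s vs %s: best lag %.2g s",
                         object$labels[1], object$labels[2],
                         object$best_lag))
}

#' Plot the repetition-by-ISI amplitude table
#' @param object an `scr_linearity`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.scr_linearity <- function(object, ...) {
  d <- object$amplitudes |>
    dplyr::group_by(.data$isi, .data$repetition) |>
    dplyr::summarise(mean_beta = mean(.data$mean_beta), .groups = "drop")
  ggplot(d, aes(x = factor(.data$isi), y = .data$mean_beta,
                fill = .data$repetition)) +
    geom_col(position = position_dodge()) +
    labs(x = "ISI (s)", y = "mean amplitude", fill = NULL)
}
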