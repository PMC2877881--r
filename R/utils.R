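#' @importFrom rlang abort warn .data %||%
#' @importFrom stats sd var optimize uniroot rnorm runif rpois qnorm
#'   pnorm dnorm t.test coef lm
#' @importFrom utils head tail packageVersion
NULL

abort_scrlti <- function(msg, class) {
  rlang::abort(msg, class = c(class, "scrlti_error"))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_number <- function(x, what, positive = FALSE, nonneg = FALSE) {
  if (!is_number(x)) {
    abort_scrlti(sprintf("`%s` must be a single finite number", what),
                 "scrlti_bad_argument")
  }
  if (positive && x <= 0) {
    abort_scrlti(sprintf("`%s` must be > 0", what), "scrlti_bad_argument")
  }
  if (nonneg && x < 0) {
    abort_scrlti(sprintf("`%s` must be >= 0", what), "scrlti_bad_argument")
  }
  invisible(x)
}

# near-integer check used wherever a duration x rate must give a sample count
as_count <- function(x, what) {
  n <- round(x)
  if (abs(x - n) > 1e-8 * max(1, abs(x))) {
    abort_scrlti(sprintf("`%s` (= %g) must be a whole number", what, x),
                 "scrlti_bad_argument")
  }
  as.integer(n)
}

fmt_num <- function(x) sprintf("%.17g", x)
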