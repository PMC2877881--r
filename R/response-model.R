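# Canonical response function (CRF): an exponentially modified Gaussian,
# i.e. the density of Gaussian(mu, sigma^2) + Exponential(mean tau). The
# fast Gaussian rise and slow exponential recovery reproduce the stereotyped
# SCR shape; time and dispersion derivatives span small latency and width
# deviations from the canonical shape.

#' Exponentially modified Gaussian density
#'
#' Density of the sum of a Gaussian (mean `mu`, sd `sigma`) and an
#' independent exponential (mean `tau`) random variable. Evaluated with the
#' scaled complementary error function on the left flank so it stays finite
#' for arguments as extreme as `|t - mu| / sigma = 40`.
#'
#' @param t evaluation times (s), vectorised.
#' @param mu Gaussian centre (s).
#' @param sigma Gaussian dispersion (s), > 0.
#' @param tau exponential mean (s), > 0.
#' @return Density values, same length as `t`.
#' @examples
#' t <- seq(0, 30, by = 0.1)
#' d <- exgauss_pdf(t, mu = 3, sigma = 0.7, tau = 1.6)
#' @export
exgauss_pdf <- function(t, mu, sigma, tau) {
  check_exgauss(sigma, tau)
  u <- (t - mu) / sigma
  z <- (sigma / tau - u) / sqrt(2)
  out <- numeric(length(t))
  left <- z >= 0 # at/left of the crossover: use erfcx to avoid erfc underflow
  if (any(left)) {
    out[left] <- exp(-u[left]^2 / 2) * erfcx_stable(z[left]) / (2 * tau)
  }
  if (any(!left)) { # right tail: plain form, exponent is negative there
    out[!left] <- exp(sigma^2 / (2 * tau^2) - (t[!left] - mu) / tau) *
      pracma::erfc(z[!left]) / (2 * tau)
  }
  out
}

# erfcx(z) = exp(z^2) erfc(z); beyond z ~ 25 the direct product overflows
# internally, so switch to the continued asymptotic expansion there
erfcx_stable <- function(z) {
  out <- numeric(length(z))
  big <- z > 25
  if (any(!big)) out[!big] <- pracma::erfcx(z[!big])
  if (any(big)) {
    zi2 <- 1 / z[big]^2
    out[big] <- (1 + zi2 * (-0.5 + zi2 * (0.75 - 1.875 * zi2))) /
      (z[big] * sqrt(pi))
  }
  out
}

check_exgauss <- function(sigma, tau) {
  stopifnot_number(sigma, "sigma", positive = TRUE)
  stopifnot_number(tau, "tau", positive = TRUE)
}

# d/dt of the density; closed form via the Gaussian density
exgauss_ddt <- function(t, mu, sigma, tau) {
  (dnorm(t, mu, sigma) - exgauss_pdf(t, mu, sigma, tau)) / tau
}

# partial derivatives wrt mu and sigma
exgauss_dmu <- function(t, mu, sigma, tau) {
  -exgauss_ddt(t, mu, sigma, tau)
}

exgauss_dsigma <- function(t, mu, sigma, tau) {
  f <- exgauss_pdf(t, mu, sigma, tau)
  N <- dnorm(t, mu, sigma)
  f * sigma / tau^2 - (N / tau) * ((t - mu) / sigma + sigma / tau)
}

# mode offset from mu (shift-invariant in mu)
exgauss_mode_offset <- function(sigma, tau) {
  stats::optimize(function(x) exgauss_pdf(x, 0, sigma, tau),
                  interval = c(-4 * sigma, 4 * sigma + 6 * tau),
                  maximum = TRUE, tol = 1e-10)$maximum
}

#' Peak (mode) time of the CRF
#' @param params a [crf_params] object.
#' @return Mode of the density in seconds.
#' @export
crf_mode <- function(params) {
  params$mu + exgauss_mode_offset(params$sigma, params$tau)
}

#' Solve for the Gaussian centre giving a target peak latency
#'
#' The exGaussian mode is `mu` plus a fixed offset determined by `sigma` and
#' `tau`, so the centre reproducing a target peak time has a direct solution.
#' This is the calibration used for the default CRF parameters (palmar peak
#' latency 3.9 s) and the finger (4.3 s) and foot (5.0 s) presets.
#'
#' @param peak_time target mode in seconds.
#' @param sigma Gaussian dispersion (s).
#' @param tau exponential mean (s).
#' @return The calibrated `mu` in seconds.
#' @export
crf_calibrate_mu <- function(peak_time, sigma = 0.7, tau = 1.6) {
  check_exgauss(sigma, tau)
  stopifnot_number(peak_time, "peak_time")
  peak_time - exgauss_mode_offset(sigma, tau)
}

#' CRF parameter set
#'
#' Parameters of the exponentially modified Gaussian canonical response
#' function. When `mu` is omitted it is calibrated so the mode equals
#' `peak_time` (default 3.9 s, the palmar peak latency; `sigma` = 0.7 s and
#' `tau` = 1.6 s give the characteristic fast rise and slow recovery).
#'
#' @param mu Gaussian centre (s); calibrated from `peak_time` when `NULL`.
#' @param sigma Gaussian dispersion (s), > 0.
#' @param tau exponential mean (s), > 0.
#' @param duration support length of the sampled CRF (s), must exceed `mu`.
#' @param peak_time target mode used to calibrate `mu` when `mu` is `NULL`.
#' @return An object of class `scr_crf_params`.
#' @examples
#' crf_params() # palmar default, peak at 3.9 s
#' crf_params(peak_time = 5.0) # foot preset
#' @export
crf_params <- function(mu = NULL, sigma = 0.7, tau = 1.6, duration = 30,
                       peak_time = 3.9) {
  check_exgauss(sigma, tau)
  stopifnot_number(duration, "duration", positive = TRUE)
  if (is.null(mu)) mu <- crf_calibrate_mu(peak_time, sigma, tau)
  stopifnot_number(mu, "mu")
  if (duration <= mu) {
    abort_scrlti("duration must exceed mu", "scrlti_bad_argument")
  }
  structure(list(mu = mu, sigma = sigma, tau = tau, duration = duration),
            class = "scr_crf_params")
}

#' @export
print.scr_crf_params <- function(x, ...) {
  cat(sprintf("<scr_crf_params> mu=%.4g s, sigma=%.4g s, tau=%.4g s, duration=%g s (mode %.3f s)\n",
              x$mu, x$sigma, x$tau, x$duration, crf_mode(x)))
  invisible(x)
}

#' Recording-site CRF presets
#'
#' Presets calibrated to the characteristic peak latencies of palmar
#' (3.9 s), finger (4.3 s) and plantar/foot (5.0 s) recordings.
#'
#' @param site one of `"palm"`, `"finger"`, `"foot"`.
#' @return A [crf_params] object.
#' @export
crf_site_params <- function(site = c("palm", "finger", "foot")) {
  site <- match.arg(site)
  crf_params(peak_time = c(palm = 3.9, finger = 4.3, foot = 5.0)[[site]])
}

crf_grid <- function(params, fs) {
  stopifnot_number(fs, "fs", positive = TRUE)
  n <- as_count(params$duration * fs, "duration * fs")
  (seq_len(n) - 1) / fs
}

#' Sampled canonical response function
#'
#' Samples the exGaussian density on `[0, duration)` at `fs` and
#' peak-normalises so the maximum sample equals 1; GLM amplitude estimates
#' are then in the units of the analysed signal.
#'
#' @param params a [crf_params] object.
#' @param fs sampling rate (Hz); `duration * fs` must be a whole number.
#' @return Numeric vector of length `duration * fs`, maximum exactly 1.
#' @export
crf <- function(params = crf_params(), fs = 10) {
  tt <- crf_grid(params, fs)
  v <- exgauss_pdf(tt, params$mu, params$sigma, params$tau)
  v / max(v)
}

# derivative of the peak-normalised sampled CRF wrt a parameter. The
# normaliser is the value at the argmax sample, a fixed grid point, so its
# parameter-derivative is just the density derivative there (exact away from
# argmax switch points).
normalised_derivative <- function(params, fs, dfun) {
  tt <- crf_grid(params, fs)
  f <- exgauss_pdf(tt, params$mu, params$sigma, params$tau)
  g <- dfun(tt, params$mu, params$sigma, params$tau)
  i <- which.max(f)
  (g * f[i] - f * g[i]) / f[i]^2
}

#' Time and dispersion derivatives of the CRF
#'
#' Analytic partial derivatives of the peak-normalised sampled CRF with
#' respect to the Gaussian centre `mu` (latency shifts) and dispersion
#' `sigma` (width changes), used as additional basis functions to absorb
#' small shape deviations between participants and conditions.
#'
#' @inheritParams crf
#' @return Numeric vector of length `duration * fs`.
#' @export
time_derivative <- function(params = crf_params(), fs = 10) {
  normalised_derivative(params, fs, exgauss_dmu)
}

#' @rdname time_derivative
#' @export
dispersion_derivative <- function(params = crf_params(), fs = 10) {
  normalised_derivative(params, fs, exgauss_dsigma)
}

#' Build a CRF basis set
#'
#' Assembles the sampled CRF and, optionally, its time and dispersion
#' derivatives into a basis-function matrix for convolution designs. With
#' `orthogonalise = TRUE` the derivative rows are sequentially projected off
#' the earlier rows (Gram-Schmidt) and unit-normalised; this changes the
#' individual regressors but not the spanned column space, so fitted values
#' are identical either way.
#'
#' @inheritParams crf
#' @param include_derivatives include the two derivative rows (default TRUE).
#' @param orthogonalise orthogonalise derivative rows to earlier rows.
#' @return An object of class `scr_basis`: fields `matrix` (n_basis rows x
#'   n_samples), `names`, `fs`, `params`, `normalisation`.
#' @examples
#' b <- build_basis(crf_params(), fs = 10)
#' tibble::as_tibble(b)
#' @export
build_basis <- function(params = crf_params(), fs = 10,
                        include_derivatives = TRUE, orthogonalise = FALSE) {
  rows <- list(crf = crf(params, fs))
  if (include_derivatives) {
    rows$time_derivative <- time_derivative(params, fs)
    rows$dispersion_derivative <- dispersion_derivative(params, fs)
  }
  m <- do.call(rbind, rows)
  norm_desc <- "crf peak-normalised to max 1"
  if (orthogonalise && nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      for (j in 1:(i - 1)) {
        m[i, ] <- m[i, ] - sum(m[i, ] * m[j, ]) / sum(m[j, ]^2) * m[j, ]
      }
      m[i, ] <- m[i, ] / sqrt(sum(m[i, ]^2))
    }
    norm_desc <- paste(norm_desc,
                       "; derivatives Gram-Schmidt orthogonalised, unit norm")
  }
  structure(list(matrix = m, names = rownames(m), fs = as.numeric(fs),
                 params = params, normalisation = norm_desc,
                 orthogonalised = isTRUE(orthogonalise)),
            class = "scr_basis")
}

#' @export
print.scr_basis <- function(x, ...) {
  cat(sprintf("<scr_basis> %d function(s) x %d samples @ %g Hz (%s)\n",
              nrow(x$matrix), ncol(x$matrix), x$fs, x$normalisation))
  invisible(x)
}

#' Basis set as a long tibble
#' @param x an `scr_basis`.
#' @param ... unused.
#' @export
as_tibble.scr_basis <- function(x, ...) {
  m <- ncol(x$matrix)
  tibble::tibble(
    name = rep(x$names, each = m),
    time = rep((seq_len(m) - 1) / x$fs, times = nrow(x$matrix)),
    value = as.vector(t(x$matrix)))
}

#' Read/write a basis set as delimited text
#' @param x an `scr_basis`.
#' @param path file path.
#' @return `write_basis`: `path` invisibly; `read_basis`: an `scr_basis`.
#' @export
write_basis <- function(x, path) {
  stopifnot(inherits(x, "scr_basis"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%s", fmt_num(x$fs)),
               sprintf("# names=%s", paste(x$names, collapse = ",")),
               sprintf("# normalisation=%s", x$normalisation)), con)
  writeLines(apply(x$matrix, 2, function(col)
    paste(fmt_num(col), collapse = "\t")), con)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  rec <- read_text_records(path)
  fs <- header_num(rec$header, "fs")
  if (is.null(fs)) {
    abort_scrlti("basis file must carry an fs header", "scrlti_io_error")
  }
  nm <- strsplit(rec$header$names %||% "", ",")[[1]]
  m <- t(vapply(strsplit(rec$lines, "\t", fixed = TRUE),
                function(r) as.numeric(r), numeric(length(nm))))
  m <- t(m)
  rownames(m) <- nm
  structure(list(matrix = m, names = nm, fs = fs, params = NULL,
                 normalisation = rec$header$normalisation %||% "unknown",
                 orthogonalised = NA),
            class = "scr_basis")
}
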