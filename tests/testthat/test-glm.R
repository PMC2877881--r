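toy_basis <- function(v = c(0, 1, 2, 1, 0.5), fs = 10) {
  structure(list(matrix = matrix(v, 1), names = "b", fs = fs, params = NULL,
                 normalisation = "toy", orthogonalised = FALSE),
            class = "scr_basis")
}

test_that("design columns are shifted truncated copies of the basis", {
  b <- toy_basis()
  d0 <- build_design(scr_events(0), b, n_samples = 10, fs = 10)
  expect_equal(ncol(d0$X), 2) # one event x one basis + constant
  expect_equal(unname(d0$X[, 1]), c(0, 1, 2, 1, 0.5, rep(0, 5)))
  expect_equal(unname(d0$X[, 2]), rep(1, 10))

  d2 <- build_design(scr_events(2), b, n_samples = 30, fs = 10)
  expect_equal(unname(d2$X[, 1]),
               c(rep(0, 20), c(0, 1, 2, 1, 0.5), rep(0, 5)))
})

test_that("overlapping events superpose in a shared-label design", {
  b <- toy_basis()
  d <- build_design(scr_events(c(0, 0.2), labels = c("x", "x")), b,
                    n_samples = 10, fs = 10, per_event = FALSE)
  one <- build_design(scr_events(0), b, 10, 10)$X[, 1]
  two <- build_design(scr_events(0.2), b, 10, 10)$X[, 1]
  expect_equal(unname(d$X[, 1]), unname(one + two))
  # per-event designs keep the events in separate columns
  dp <- build_design(scr_events(c(0, 0.2)), b, 10, 10, per_event = TRUE)
  expect_equal(ncol(dp$X), 3)
})

test_that("design validation catches bad inputs", {
  b <- toy_basis()
  expect_error(build_design(scr_events(5), b, n_samples = 10, fs = 10),
               class = "scrlti_bad_events") # onset outside range
  expect_error(build_design(scr_events(0), b, n_samples = 10, fs = 20),
               class = "scrlti_bad_argument") # fs mismatch
})

test_that("noiseless fits recover the generating coefficients exactly", {
  b <- toy_basis()
  d <- build_design(scr_events(c(0, 1.5)), b, n_samples = 50, fs = 10)
  y <- 2.0 * d$X[, 1] + 0.7 * d$X[, 2] + 0.5
  fit <- fit_glm(y, d)
  expect_equal(unname(fit$beta), c(2.0, 0.7, 0.5), tolerance = 1e-9)
  expect_equal(fit$fitted + fit$residuals, y)
  expect_lt(max(abs(crossprod(d$X, fit$residuals))),
            1e-8 * max(sqrt(colSums(d$X^2))) * sqrt(sum(y^2) + 1))
})

test_that("noise orthogonal to the design yields zero coefficients", {
  set.seed(61)
  b <- toy_basis()
  d <- build_design(scr_events(1), b, n_samples = 50, fs = 10)
  e <- rnorm(50)
  e <- e - d$X %*% qr.coef(qr(d$X), e) # orthogonalise against X
  fit <- fit_glm(drop(e), d)
  expect_lt(max(abs(fit$beta)), 1e-9)
})

test_that("coefficients match the normal-equations oracle", {
  set.seed(62)
  b <- build_basis(crf_params(peak_time = 1.5, sigma = 0.3, tau = 0.5,
                              duration = 3), fs = 10)
  d <- build_design(scr_events(c(0.3, 1.8)), b, n_samples = 50, fs = 10)
  y <- rnorm(50)
  oracle <- solve(crossprod(d$X), crossprod(d$X, y))
  fit <- fit_glm(y, d)
  expect_equal(unname(fit$beta), unname(drop(oracle)), tolerance = 1e-8)
  expect_equal(fit$explained, 1 - sum(fit$residuals^2) / sum((y - mean(y))^2))
})

test_that("coincident events make the design rank deficient", {
  b <- toy_basis()
  ev <- scr_events(c(0.95, 1)) # both land on the same 10 Hz sample
  d <- build_design(ev, b, n_samples = 30, fs = 10)
  expect_error(fit_glm(rnorm(30), d), class = "scrlti_rank_deficient")
})

test_that("betas are equivariant to delaying events and signal together", {
  b <- toy_basis()
  d1 <- build_design(scr_events(c(0.5, 2)), b, n_samples = 80, fs = 10)
  y1 <- 1.3 * d1$X[, 1] + 0.8 * d1$X[, 2] + 0.2
  k <- 7 # samples
  d2 <- build_design(scr_events(c(0.5, 2) + k / 10), b,
                     n_samples = 80 + k, fs = 10)
  y2 <- c(rep(0.2, k), y1) # shifted signal, constant fills the gap
  expect_equal(unname(fit_glm(y2, d2)$beta[1:2]),
               unname(fit_glm(y1, d1)$beta[1:2]), tolerance = 1e-10)
})

test_that("residual variance decreases monotonically in nested bases", {
  set.seed(63)
  p <- crf_params()
  y <- 2 * crf(p, 10) + 0.5 * time_derivative(p, 10) + rnorm(300, 0, 0.2)
  rss <- vapply(c(FALSE, TRUE), function(derivs) {
    b <- build_basis(p, 10, include_derivatives = derivs)
    d <- build_design(scr_events(0), b, n_samples = 300, fs = 10)
    sum(fit_glm(y, d)$residuals^2)
  }, numeric(1))
  expect_lt(rss[2], rss[1])
})

test_that("superposition holds exactly for same-basis generated data", {
  # the core LTI claim: overlapping events fitted by the generating basis
  # return the generating amplitudes, at every ISI down to one sample
  b <- build_basis(crf_params(), fs = 10, include_derivatives = FALSE)
  for (isi in c(0.1, 2, 5.5, 9)) {
    d <- build_design(scr_events(c(1, 1 + isi)), b, n_samples = 450, fs = 10)
    y <- 1.1 * d$X[, 1] + 0.6 * d$X[, 2] + 0.05
    fit <- fit_glm(y, d)
    expect_equal(unname(fit$beta), c(1.1, 0.6, 0.05), tolerance = 1e-8)
  }
})

linearity_on <- function(cfg, subject = "s1") {
  out <- simulate_scr(cfg)
  sig <- downsample(out$signal, 10)
  lep <- linearity_epochs(sig, out$truth, subject = subject,
                          mean_centre = FALSE)
  linearity_analysis(lep$single, lep$double)
}

test_that("the linearity pipeline is exact on isolated clean trials", {
  # without filtering or trial overlap, the per-subject PC1 equals the
  # generating template and the fits recover the suppression factor exactly
  lin <- linearity_analysis(
    bind_epochs(lapply(1:3, function(s) {
      cfg <- isolated_paired_config(
        seed = 70 + s,
        suppression = list(factor = 0.7, isi_dependent = FALSE,
                           isi_scale = 5))
      out <- simulate_scr(cfg)
      linearity_epochs(downsample(out$signal, 10), out$truth,
                       subject = sprintf("s%d", s),
                       mean_centre = FALSE)$single
    })),
    bind_epochs(lapply(1:3, function(s) {
      cfg <- isolated_paired_config(
        seed = 70 + s,
        suppression = list(factor = 0.7, isi_dependent = FALSE,
                           isi_scale = 5))
      out <- simulate_scr(cfg)
      linearity_epochs(downsample(out$signal, 10), out$truth,
                       subject = sprintf("s%d", s),
                       mean_centre = FALSE)$double
    })))
  expect_equal(lin$ratios$ratio, rep(0.7, 3), tolerance = 1e-8)
  expect_equal(lin$ratio_isi_trend, 0, tolerance = 1e-8)
  # shared trial amplitudes make the within-subject slope the suppression
  pooled <- lin$slope_tests[lin$slope_tests$scope == "pooled", ]
  expect_equal(pooled$mean_slope, 0.7, tolerance = 1e-8)
  # consistently positive across subjects (NA t = numerically zero spread)
  expect_true(is.na(pooled$t) || pooled$t > 10)
})

test_that("ISI-dependent suppression is recovered per ISI on isolated trials", {
  lin <- linearity_on(isolated_paired_config(
    seed = 80, suppression = list(factor = 0.9, isi_dependent = TRUE,
                                  isi_scale = 10)))
  expect_equal(lin$ratios$ratio, 0.9 * exp(-c(2, 5.5, 9) / 10),
               tolerance = 1e-8)
})

test_that("the packed paired design adds only a small overlap distortion", {
  # with the standard 30-40 s inter-trial silences, a 39 s double epoch can
  # graze the next trial's response; on clean unfiltered data this shifts
  # the recovered ratio by well under the analysis' resolution
  lin <- run_linearity_study(3, seed0 = 70, chain = "raw", n_per = 4)
  expect_equal(lin$ratios$ratio, rep(0.7, 3), tolerance = 0.03)
  expect_lt(abs(lin$ratio_isi_trend), 0.005)
})

test_that("linearity analysis validates its inputs", {
  lep <- paired_subject(seed = 90, subject = "s1", chain = "raw", n_per = 2)
  no_isi <- lep$double
  no_isi$meta$isi <- NULL
  expect_error(linearity_analysis(lep$single, no_isi),
               class = "scrlti_bad_epochs")
})
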