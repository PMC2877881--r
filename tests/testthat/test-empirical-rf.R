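test_that("rank-one epoch sets are explained exactly by one component", {
  ep <- rank1_epochs(amps = c(1, 2, -0.5, 3))
  p <- epoch_pca(ep, k = 2)
  expect_equal(p$explained_fraction[1], 1, tolerance = 1e-12)
  shape <- ep$data[1, ] / sqrt(sum(ep$data[1, ]^2))
  expect_gt(abs(sum(p$components[1, ] * shape)), 1 - 1e-12)
  # orientation: the largest-magnitude sample is positive
  expect_gt(p$components[1, which.max(abs(p$components[1, ]))], 0)
})

test_that("the first component converges to the true shape under noise", {
  set.seed(21)
  n <- 100; m <- 300
  shape <- crf(crf_params(), 10); shape <- shape - mean(shape)
  v <- shape / sqrt(sum(shape^2))
  amps <- rnorm(n, 5, 1) # SNR ~10 against unit-variance-ish noise rows
  X <- outer(amps, v) * sqrt(m)
  X <- X + matrix(rnorm(n * m, 0, sqrt(mean(X^2) / 10)), n, m)
  p <- epoch_pca(scr_epochs(X, 10, 30), k = 1)
  expect_gt(abs(sum(p$components[1, ] * v)), 0.99)
})

test_that("epoch_pca matches a dense second-moment eigendecomposition", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(20 * 50), 20, 50) +
      outer(runif(20, 0.5, 2), sin(seq(0, 3 * pi, length.out = 50)))
    X <- X - rowMeans(X)
    ep <- scr_epochs(X, fs = 10, epoch_len = 5)
    p <- epoch_pca(ep, k = 3)
    # oracle: explicit n_samples x n_samples second-moment matrix
    M <- crossprod(X) / nrow(X)
    eig <- eigen(M, symmetric = TRUE)
    expect_equal(p$eigenvalues, eig$values[1:3], tolerance = 1e-8)
    expect_equal(p$explained_fraction,
                 eig$values[1:3] / sum(diag(M)), tolerance = 1e-8)
    for (i in 1:3) { # components agree up to sign
      expect_gt(abs(sum(p$components[i, ] * eig$vectors[, i])), 1 - 1e-8)
    }
  }
})

test_that("epoch_pca validates its inputs", {
  ep <- rank1_epochs(c(1, 2))
  expect_error(epoch_pca(ep, k = 3), class = "scrlti_bad_argument")
  z <- scr_epochs(matrix(0, 3, 10), 10, 1)
  expect_error(epoch_pca(z, 1), class = "scrlti_bad_epochs")
  one <- scr_epochs(matrix(rnorm(10), 1, 10), 10, 1)
  expect_error(epoch_pca(one, 1), class = "scrlti_bad_epochs")
})

test_that("excluded epochs do not contribute to the decomposition", {
  ep <- rank1_epochs(c(1, 2, 3))
  ep$meta$excluded[2] <- TRUE
  ep$data[2, ] <- 99 # garbage that must be ignored
  p <- epoch_pca(ep, k = 1)
  expect_equal(p$n_epochs, 2)
  expect_equal(p$explained_fraction[1], 1, tolerance = 1e-12)
})

test_that("explained fractions are invariant to reordering and scaling", {
  set.seed(5)
  X <- matrix(rnorm(12 * 40), 12, 40); X <- X - rowMeans(X)
  p1 <- epoch_pca(scr_epochs(X, 10, 4), k = 2)
  p2 <- epoch_pca(scr_epochs(X[sample(12), ] * 7, 10, 4), k = 2)
  expect_equal(p1$explained_fraction, p2$explained_fraction,
               tolerance = 1e-10)
})

test_that("a shared noiseless shape gives a pure common partition", {
  sh <- sin(seq(0, 2 * pi, length.out = 50)); sh <- sh - mean(sh)
  eps <- lapply(1:3, function(s) {
    scr_epochs(outer(c(1, 2, 1.5) * s, sh), 10, 5,
               meta = tibble::tibble(subject = rep(paste0("s", s), 3)))
  })
  vp <- variance_partition(eps)
  expect_equal(vp$common, 1, tolerance = 1e-9)
  expect_equal(vp$between_subjects, 0, tolerance = 1e-9)
  expect_equal(vp$residual, 0, tolerance = 1e-9)
})

test_that("orthogonal subject shapes split variance between common and between", {
  # two subjects with orthogonal noiseless shapes of equal total variance:
  # pooled PC1 can explain exactly half, each subject's own PC1 all of it
  n <- 50
  s1 <- sin(seq(0, 2 * pi, length.out = n)); s1 <- s1 - mean(s1)
  s2 <- cos(seq(0, 4 * pi, length.out = n)); s2 <- s2 - mean(s2)
  s2 <- s2 - s1 * sum(s1 * s2) / sum(s1^2) # force exact orthogonality
  s1 <- s1 / sqrt(sum(s1^2)); s2 <- s2 / sqrt(sum(s2^2))
  amps <- c(1, 1, 1)
  eps <- list(
    scr_epochs(outer(amps, s1), 10, 5,
               meta = tibble::tibble(subject = rep("a", 3))),
    scr_epochs(outer(amps, s2), 10, 5,
               meta = tibble::tibble(subject = rep("b", 3))))
  vp <- variance_partition(eps)
  expect_equal(vp$per_subject$explained, c(1, 1), tolerance = 1e-9)
  expect_equal(vp$common, 0.5, tolerance = 1e-9)
  expect_equal(vp$between_subjects, 0.5, tolerance = 1e-9)
  expect_equal(vp$residual, 0, tolerance = 1e-9)
})

test_that("partition components decompose the pooled variance exactly", {
  set.seed(9)
  eps <- lapply(1:4, function(s) {
    X <- matrix(rnorm(8 * 30), 8, 30); X <- X - rowMeans(X)
    scr_epochs(X, 10, 3, meta = tibble::tibble(subject = rep(paste0("s", s), 8)))
  })
  vp <- variance_partition(eps)
  expect_equal(vp$common + vp$between_subjects + vp$residual, 1,
               tolerance = 1e-9)
  # each subject's own PC1 is optimal for that subject
  expect_gte(vp$between_subjects, -1e-9)
})

test_that("baseline variance ratios scale quadratically", {
  ep <- rank1_epochs(c(1, 2, 3))
  expect_equal(baseline_ratio(ep, ep), 1)
  half <- scr_epochs(ep$data * 0.5, ep$fs, ep$epoch_len)
  expect_equal(baseline_ratio(ep, half), 0.25)
  zero <- scr_epochs(matrix(0, 2, ncol(ep$data)), ep$fs, ep$epoch_len)
  expect_error(baseline_ratio(zero, ep), class = "scrlti_bad_epochs")
})

test_that("spontaneous-only baselines explain evoked-model residuals", {
  # evoked epochs carry responses + spontaneous activity; baseline epochs
  # only spontaneous activity. The baseline/evoked variance ratio must
  # exceed the residual fraction of the evoked decomposition when
  # spontaneous fluctuations dominate the noise.
  cfg <- scenario("time_invariant", seed = 31, n_events = 15,
                  spont_rate = 1 / 15, noise_sd = 0.01)
  out <- simulate_scr(cfg)
  # append a quiet baseline stretch with spontaneous activity only
  base_cfg <- sim_config(fs = 100, duration = 240, event_onsets = numeric(0),
                         spont_rate = 1 / 15, noise_sd = 0.01, seed = 32)
  base_out <- simulate_scr(base_cfg)
  joined <- scr_signal(c(out$signal$values, base_out$signal$values), fs = 100)
  ev <- sim_events(cfg)
  base_onsets <- out$truth$config$duration + seq(2, 180, by = 30)
  pp <- preprocess_chain(joined, ev)
  evoked <- pp$epochs
  baseline <- extract_epochs(pp$signal, scr_events(base_onsets))
  ratio <- baseline_ratio(evoked, baseline)
  resid <- 1 - epoch_pca(evoked, 1)$explained_fraction[1]
  expect_lt(ratio, 1)
  expect_gt(ratio, resid)
})

test_that("the high-pass sweep reruns the chain per cut-off", {
  cfg <- clean_config(duration = 400, event_onsets = seq(20, 340, by = 45),
                      amplitude = c(1, 0.3), seed = 41)
  out <- simulate_scr(cfg)
  sw <- filter_sweep(out$signal, sim_events(cfg))
  expect_equal(nrow(sw), 6)
  expect_equal(sw$cutoff, seq(0, 0.025, by = 0.005))
  # noiseless constant-shape simulation: explained ~1 at every cut-off
  expect_true(all(sw$explained > 0.999))
  expect_error(filter_sweep(out$signal, sim_events(cfg), cutoffs = c(0, 6)),
               class = "scrlti_bad_filter")
})

test_that("explained variance varies smoothly with the cut-off under drift", {
  cfg <- sim_config(duration = 400, event_onsets = seq(20, 340, by = 45),
                    amplitude = c(1, 0.3), spont_rate = 1 / 30,
                    tonic = list(rw_sd = 5e-4, n_sines = 2, max_amp = 0.2),
                    noise_sd = 0.02, seed = 42)
  out <- simulate_scr(cfg)
  sw <- filter_sweep(out$signal, sim_events(cfg))
  expect_true(all(abs(diff(sw$explained)) < 0.05))
})

test_that("lagged correlation recovers constructed lags and invariances", {
  set.seed(51)
  n <- 2000
  base <- as.numeric(stats::filter(rnorm(n + 13), rep(1, 8) / 8,
                                   sides = 1))[14:(n + 13)]
  a <- scr_signal(base, fs = 10, label = "palm")
  expect_equal(lagged_correlation(a, a)$best_lag, 0)
  expect_equal(lagged_correlation(a, a)$best_r2, 1, tolerance = 1e-12)

  b <- scr_signal(c(rep(0, 13), base)[1:n], fs = 10, label = "finger")
  lc <- lagged_correlation(a, b, max_lag = 5)
  expect_equal(lc$best_lag, 1.3) # 13 samples at 10 Hz, exactly
  expect_gt(lc$best_r2, 0.99)

  neg <- scr_signal(-2 * base + 5, fs = 10)
  lc2 <- lagged_correlation(a, neg)
  expect_equal(lc2$best_lag, 0)
  expect_equal(lc2$best_r2, 1, tolerance = 1e-12)

  expect_error(lagged_correlation(a, scr_signal(rep(1, n), fs = 10)),
               class = "scrlti_bad_signal")
  expect_error(lagged_correlation(a, scr_signal(base, fs = 20)),
               class = "scrlti_bad_argument")
  short <- scr_signal(base[1:30], fs = 10)
  expect_error(lagged_correlation(short, short, max_lag = 5),
               class = "scrlti_bad_argument")
})
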