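# shared fixtures: small deterministic objects built in code

# a clean simulation config: evoked responses only
clean_config <- function(...) {
  defaults <- list(noise_sd = 0, spont_rate = 0,
                   tonic = list(rw_sd = 0, n_sines = 0, max_amp = 0),
                   shape_jitter = c(0, 0))
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# epochs = outer(amps, shape): exactly rank one, rows mean-centred via shape
rank1_epochs <- function(amps, n_samples = 50, fs = 10, seed = 1) {
  set.seed(seed)
  shape <- sin(seq(0, 2 * pi, length.out = n_samples))
  shape <- shape - mean(shape)
  scr_epochs(outer(amps, shape), fs = fs, epoch_len = n_samples / fs)
}

# stack per-subject epoch objects into one
bind_epochs <- function(lst) {
  scr_epochs(do.call(rbind, lapply(lst, function(e) e$data)),
             fs = lst[[1]]$fs, epoch_len = lst[[1]]$epoch_len,
             meta = dplyr::bind_rows(lapply(lst, function(e) e$meta)))
}

# simulate a paired-design subject and return linearity epochs through the
# given preprocessing. chain = "raw" silences every noise source and skips
# mean-centring, so the template is fully identified and the pipeline exact
paired_subject <- function(seed, subject, scenario_name = "nonlinear_suppression",
                           chain = c("full", "raw"), ...) {
  chain <- match.arg(chain)
  args <- list(...)
  if (chain == "raw") {
    args <- utils::modifyList(
      list(noise_sd = 0, spont_rate = 0,
           tonic = list(rw_sd = 0, n_sines = 0, max_amp = 0)), args)
  }
  cfg <- do.call(scenario, c(list(scenario_name, seed = seed), args))
  out <- simulate_scr(cfg)
  sig <- switch(chain,
                full = ztransform(downsample(bandpass(out$signal), 10)),
                raw = downsample(out$signal, 10))
  linearity_epochs(sig, out$truth, subject = subject,
                   mean_centre = chain == "full")
}

# paired design with trials spaced so widely that no 39-s double epoch can
# touch a neighbouring trial: isolates the estimator from overlap effects
isolated_paired_config <- function(seed, n_per = 3, isis = c(2, 5.5, 9),
                                   gap = 50, ...) {
  onsets <- numeric(0); labels <- character(0); trials <- integer(0)
  t_cur <- 2; tr <- 0L
  for (rep in seq_len(n_per)) {
    tr <- tr + 1L
    onsets <- c(onsets, t_cur); labels <- c(labels, "single")
    trials <- c(trials, tr); t_cur <- t_cur + gap
    for (isi in isis) {
      tr <- tr + 1L
      onsets <- c(onsets, t_cur, t_cur + isi)
      labels <- c(labels, sprintf("first_isi%g", isi),
                  sprintf("second_isi%g", isi))
      trials <- c(trials, tr, tr)
      t_cur <- t_cur + isi + gap
    }
  }
  clean_config(duration = t_cur + 2, event_onsets = onsets,
               event_labels = labels, event_trials = trials, seed = seed, ...)
}

run_linearity_study <- function(n_subjects, seed0, chain = "full", ...) {
  res <- lapply(seq_len(n_subjects), function(s) {
    paired_subject(seed = seed0 + s, subject = sprintf("s%02d", s),
                   chain = chain, ...)
  })
  linearity_analysis(bind_epochs(lapply(res, `[[`, "single")),
                     bind_epochs(lapply(res, `[[`, "double")))
}
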