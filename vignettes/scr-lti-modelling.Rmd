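---
title: "Modelling event-related skin conductance responses as an LTI system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling event-related skin conductance responses as an LTI system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(scrlti)
```

## The model

Event-related skin conductance responses (SCRs) are driven by brief bursts
of sudomotor nerve activity. The working model of this package treats the
peripheral system that turns those bursts into measurable conductance
changes as **linear and time-invariant (LTI)**:

* *time-invariance* — within a person (and recording site), every evoked
  response is a scaled copy of one template, the response function
  $h(t)$;
* *linearity* — when responses overlap, the compound signal is the sum of
  the individual responses.

Under these assumptions the observed signal is a convolution

$$ y(t) \;=\; \sum_i a_i\, h(t - t_i) \;+\; \text{tonic}(t) \;+\; \varepsilon(t), $$

where $t_i$ are event onsets and the amplitudes $a_i$ index sympathetic
arousal. Amplitude estimation then becomes a general linear model: each
onset contributes a "stick function" (unit impulse) convolved with the
template, plus a constant per analysis window.

Both assumptions are empirically testable, and the package implements the
full test battery: principal-component estimation of $h$ with variance
partitioning (time-invariance), paired-stimulus designs with
repetition-by-ISI analysis (linearity), and cross-site lag analysis
(generalisation across recording sites). Because no public recordings
accompany this problem, a synthetic generator with exact ground truth is a
first-class part of the package; every analysis stage is validated against
it.

## The canonical response function

The stereotyped SCR shape — steep rise, slow recovery — is modelled
analytically as an **exponentially modified Gaussian**: the density of
$\mathcal N(\mu, \sigma^2) + \mathrm{Exp}(\tau)$,

$$ h(t) = \frac{1}{2\tau}
   \exp\!\Big(\frac{\sigma^2}{2\tau^2} - \frac{t-\mu}{\tau}\Big)\,
   \operatorname{erfc}\!\Big(\frac{\sigma/\tau - (t-\mu)/\sigma}{\sqrt 2}\Big). $$

The Gaussian part absorbs conduction and secretion latency spread; the
exponential part the slow recovery. Numerically the left flank is evaluated
through the scaled complementary error function (`erfcx`), with an
asymptotic continued expansion beyond $z = 25$, so the density stays finite
for standardised arguments up to $\pm 40$.

**Parameter defaults.** The three parameters are user-facing and have
units of seconds. The defaults are calibrated, not copied: with
$\sigma = 0.7$ s and $\tau = 1.6$ s (a fast rise and a recovery much longer
than the rise), $\mu$ is solved so that the mode of the density equals the
characteristic palmar peak latency of 3.9 s. Because the mode is $\mu$ plus
an offset that depends only on $(\sigma, \tau)$, the calibration is a
direct solve (`crf_calibrate_mu()`), and presets for finger (4.3 s) and
foot (5.0 s) recordings are provided. The sampled CRF is
**peak-normalised** (maximum sample = 1) so GLM amplitudes are in the units
of the analysed signal; an area-normalisation would have been equally
defensible but makes amplitudes harder to read.

```{r crf}
p <- crf_params()
p
autoplot(build_basis(p, fs = 10))
```

**Derivative basis functions.** Small deviations in latency and width are
absorbed by two extra regressors: the analytic partial derivatives of the
peak-normalised CRF with respect to $\mu$ (time derivative) and $\sigma$
(dispersion derivative). We chose analytic derivatives — the standard
informed-basis-set construction — over PCA-derived ones; the derivative of
the normalisation constant is handled exactly, because the normaliser is
the density value at the fixed argmax sample, whose parameter derivative
is available in closed form. Optional Gram–Schmidt orthogonalisation
changes the individual regressors but provably not the spanned column
space; both variants are exposed because orthogonalisation changes how
variance is attributed to the canonical shape versus its derivatives.

## Preprocessing

The chain follows standard electrodermal practice, in this order:

1. **Band-pass filter** at the native rate: first-order Butterworth
   sections, high-pass 0.0159 Hz (time constant $1/(2\pi f) = 10$ s) and
   low-pass 5 Hz, each applied forward and backward ("bidirectional"), so
   the phase response is identically zero and the net magnitude response is
   the squared single-pass response. We implement the band-pass as a
   cascade of separate high- and low-pass sections rather than one biquad:
   the skirts are identical at first order, the analytic magnitude oracle
   is per-section, and the `hp_cutoff = 0` (no high-pass) case used by the
   filter sweep stays clean. Edge effects are handled by odd-symmetric
   signal extension of length $3/f_c$ seconds, capped at the signal length;
   tests only assert filter properties at least 30 s from the edges.
2. **Downsample to 10 Hz** by integer decimation (the low-pass sits well
   below the new Nyquist).
3. **z-transform** of the whole continuous series (population convention,
   divisor $n$), absorbing between-subject amplitude differences due to
   peripheral skin properties. The standardisation is shared between evoked
   and baseline segments of a recording — required for the baseline
   variance ratio to be meaningful.
4. **Epoching**: the 30 s after each onset (sample 0 = first sample at or
   after the onset, half-open window), one row per event; each row is
   mean-centred because skin conductance level differs between trials even
   after filtering. Epochs that overrun the recording or overlap a
   recording gap are flagged `excluded` and dropped from statistics, never
   silently removed.

The order matters and is pinned by a test: filtering precedes decimation
(anti-aliasing), and standardisation operates on the analysis-rate series.

A deliberate non-goal: artefact and non-response exclusion. Keeping
everything gives a conservative residual-variance estimate and cannot bias
the shape of the estimated response function, since unsystematic noise does
not enter the first principal component.

## Empirical response functions and variance partitioning

`epoch_pca()` decomposes the epochs' second-moment matrix across rows
**without column centring** (computed via the SVD of the row-centred epoch
matrix; a dense eigendecomposition serves as an independent oracle in the
tests). This is the one PCA convention under which the first component *is*
the common response template — with cross-epoch column centring, a shape
shared by all epochs would vanish into the removed mean. The first
component is oriented so its largest-magnitude sample is positive (SCRs
deflect upward), and its explained fraction is the within-subject
time-invariance summary.

`variance_partition()` splits pooled variance into three parts: explained
by one **common** response function (pooled PC1), **between-subjects**
shape variance (subject-specific PC1s beyond the common one), and
**residual**. Within-subject fractions are combined weighted by each
subject's total epoch variance — the one weighting under which the three
components decompose the pooled variance exactly and sum to 1, and under
which between-subjects variance is provably non-negative (each subject's
own PC1 is optimal for that subject). An equal-weight convention would be
defensible for the per-subject summaries but breaks the exact
decomposition.

`baseline_ratio()` compares total variance in stimulus-free baseline
epochs against evoked epochs (same standardisation). A ratio exceeding the
residual fraction of the evoked decomposition means spontaneous
fluctuations alone are a sufficient explanation of what the LTI model
leaves unexplained.

`filter_sweep()` reruns the whole chain over high-pass cut-offs 0 to
0.025 Hz in 0.005 Hz steps (0 = no high-pass) to quantify how the
filtering choice affects the apparent response.

`lagged_correlation()` scans Pearson $r^2$ between two channels over every
sample lag in $\pm$`max_lag`; ties are broken toward the smaller absolute
lag, and a positive best lag means the second channel trails the first.

## The linearity analysis

For each subject, the response function is the first principal component of
the single-stimulus epochs (peak-normalised). Every double-stimulus trial
is then fitted with a three-column design — template at the first onset,
template at the second onset (the trial's ISI: 2, 5.5 or 9 s), constant —
one design per trial, mirroring per-trial mean-centring. The report
contains the repetition × ISI amplitude table, per-ISI second/first
amplitude ratios with their trend over ISI, within-subject regression
slopes of the second on the first amplitude, and one-sample t-tests of
those slopes (per ISI and pooled). Under linearity with ISI-independent
repetition suppression, the ratio is flat in ISI; an amplitude-dependent
refractory period would drive the slopes negative. A repeated-measures
ANOVA would add nothing bespoke here — the amplitude table is the input a
user would feed to whatever omnibus test their field expects.

Double epochs span the first onset plus 30 s plus the maximum ISI, so the
second response is fully contained; the constant is per trial (a shared
session constant is the other defensible reading; per-trial matches the
per-trial mean-centring already applied). Flat, non-responsive trials are
kept — excluding them would bias the slope regressions.

## The synthetic generator

`simulate_scr()` renders a recording as the *exact* sum of four
components, each returned as ground truth:

* **evoked SCRs** — scaled copies of the CRF at designed onsets. One base
  amplitude is drawn per trial from a truncated-at-zero normal (negative
  SCR amplitudes are non-physiological) and shared by the trial's events:
  the events of a trial ride on one arousal state, which is also what
  makes first and second response amplitudes positively coupled, as
  observed empirically. Repetition suppression scales repeated events'
  *generating* amplitude by a factor in $(0, 1]$ (optionally decaying with
  ISI) — modelling central adaptation while keeping each emitted waveform
  strictly LTI. Per-trial jitter of $(\mu, \sigma)$ provides controlled
  violations of time-invariance.
* **spontaneous SCRs** — a homogeneous Poisson process (default 2/min, a
  typical resting non-specific SCR rate) with smaller amplitudes (mean 0.3
  of the evoked mean), sharing the CRF shape by default.
* **tonic drift** — a random walk plus slow sines below 0.01 Hz, i.e.
  below the high-pass cut-off, so standard preprocessing largely removes
  it; its amplitude can rival the SCRs themselves.
* **white measurement noise** — default sd 0.02, small relative to unit
  evoked amplitudes, as for a well-shielded constant-voltage coupler.

Scenarios pin the validated study designs: `time_invariant` (single
stimuli separated by 29/34/39 s), `shape_jittered`, `paired_isi` (10
single + 10 double trials per ISI in randomised order, 2 s lead-in,
30/35/40 s of trailing silence per trial), `nonlinear_suppression`
(paired design with factor 0.7), and `multisite`. The multisite renderer
derives palm/finger/foot channels from **one shared physiological stream**
(evoked + spontaneous + tonic), lagged by 0/0.4/1.3 s and scaled by
1/0.60/0.33, plus channel-specific measurement noise — the sudomotor drive
is common to all sites, so only instrument noise is independent. Triple
stimulus filler trials of the original paired design are not simulated:
they exist to balance human expectancy and are never analysed.

What the generator does **not** emulate: biophysical sweat-duct dynamics,
movement artefacts, electrode drift or detachment, amplitude
non-stationarity over a session, and the empirically observed decay of
spontaneous activity during long silences (a rate hook exists but is off
by default). Passing tests therefore certify the *estimators* under the
stated signal model, not robustness to every property of field recordings.

## Numerical choices

* Non-uniform input timestamps are linearly interpolated onto a uniform
  grid at the stated rate; the slowest observed input rate is reported
  with a warning when it falls below 10 Hz (aliasing risk in pulse-coded
  acquisition).
* All text formats write 17 significant digits, so write/read round trips
  are lossless at double precision.
* Design matrices are built by direct placement of truncated shifted basis
  copies (no FFT round-off); fits use a rank-revealing QR, with an
  explicit error on rank deficiency (e.g. coincident onsets).
* Lag-search ties break toward the smaller absolute lag; PCA component
  signs orient the largest-magnitude sample positive.
* Degenerate inputs fail loudly: constant signals cannot be z-transformed
  or lag-correlated, all-zero epoch matrices cannot be decomposed, epochs
  with non-finite values must be flagged excluded.

## Validation scale and known limitations

The bundled acceptance analysis (`scripts/acceptance.R`, summarised in the
README) uses 20 simulated subjects × 10 trials per condition for the
linearity study, 100 epochs × 300 samples for noise-fraction recovery, and
50 random simulations for the variance-partition identities — sizes chosen
to match the validated designs while keeping a full run around ten
seconds.

One limitation deserves emphasis. The zero-phase (bidirectional) high-pass
gives every response a long undershoot that is *symmetric in time*: part
of it precedes the onset (about a tenth of the peak just before onset,
with the default 10 s time constant; our implementation agrees with the
reference forward–backward filter of `scipy.signal` to $10^{-10}$). A
post-onset 30 s response template cannot represent the second stimulus'
anticausal dip, which lands on the first response's peak in a paired
trial. The double-trial amplitude fits therefore carry a small systematic,
ISI-patterned distortion even on noiseless data — the within-window
template-mean term removed by per-trial centring contributes a further,
smaller window-step misfit. The package's own acceptance run computes the
resulting recovered ratios for a true suppression factor of 0.7, and the
exactness of the estimator absent these filter effects is established
separately on unfiltered isolated trials (to $10^{-8}$). Users comparing
first/second amplitude ratios across ISI conditions should treat
differences of a few hundredths as within the method's systematic
envelope. Relaxing the need for filtering — e.g. modelling tonic level
explicitly instead of removing it — is the natural next refinement.
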