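---
title: "Methods: sensor-space MEG analysis of covert and overt speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensor-space MEG analysis of covert and overt speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(megspeech)
```

## What this package computes

`megspeech` compares two participant cohorts — healthy controls and
patients with a motor-neuron disease such as ALS — from epoched MEG
gradiometer recordings collected during a delayed-reading speech task.
Each trial spans −0.5 to +4.5 s around stimulus onset; the *covert*
(imagined-speech) window is 1–2 s and the *overt* (articulation) window
2–4.5 s.  Four sensor-space analyses are run per window:

1. **Sensor correlation.** Pearson correlation between every pair of
   channel signals, computed per trial and averaged arithmetically,
   summarized per participant and phrase as a *correlation density*
   (mean |r| over the 19110 sensor pairs at full scale) and a
   strong-pair count (|r| > 0.5).  Cohorts are compared with one-sided
   pooled-variance t-tests on the participant × phrase summaries
   (15 per cohort at full scale, hence df = 28).
2. **Band-power distances.** Welch band power in the six canonical
   bands — delta 1–4, theta 4–8, alpha 8–16, beta 16–30, gamma 30–59
   and high gamma 61–119 Hz — averaged over trials and participants per
   cohort and phrase; each healthy-sensor × patient-sensor cell gets
   the Euclidean distance between the cohort means (the absolute
   difference for scalar per-phrase powers; the 5-phrase vector norm in
   the across-phrase variant).  Bands are compared by one-way ANOVA
   with phrases as samples, followed by Tukey's HSD.
3. **Functional connectivity.** Amplitude envelope correlation (AEC):
   each channel is band-passed with a zero-phase 4th-order Butterworth
   filter, the Hilbert envelope is extracted, and envelopes are
   correlated across channel pairs — per trial and averaged, or after
   temporal concatenation of the band-passed trials.  The signed mean
   off-diagonal value (*connectivity density*) is compared across
   cohorts with a one-sided t-test.
4. **Single-trial classification.** Regularized LDA on per-channel
   band-power features, with covariance shrinkage toward the diagonal
   (`gamma`) and a coefficient threshold (`delta`), tuned by grid
   search under stratified 10-fold cross-validation on training data
   only, evaluated with leave-one-participant-pair-out cross-validation:
   every (healthy, patient) pair is held out in turn, so 3+3
   participants give 9 folds, each training on 1200 trials and testing
   on 600 at full scale.  The summary is the median fold accuracy per
   band.

Because no recorded dataset ships with the package, a synthetic
two-cohort generator provides data with the statistical structure these
analyses assume; everything downstream of the generator treats its
output exactly as it would treat recordings imported from a file.

## The synthetic generator

Each channel of each trial is

$$x_c(t) = \sum_b \left[ \sigma_b\, s_{c,b}(t) + \rho\, \sigma_b\,
  s^{\mathrm{shared}}_b(t) \right] + \mathrm{pink}(t) +
  A_{\mathrm{line}} \sin(2\pi\,60\,t + \varphi),$$

where the $s_{c,b}$ are independent band-limited unit-variance Gaussian
sources (one per canonical band $b$), $s^{\mathrm{shared}}_b$ is a
single per-trial source added to *all* channels with coupling weight
$\rho \in [0, 1)$, the pink background has a $1/f$ spectrum above 1 Hz,
and the line term is a common-mode 60 Hz sinusoid with a random phase
per trial.  The patient cohort multiplies its beta amplitude by
$g_\beta \ge 1$ and may use a larger $\rho$.  The overt window (2–4.5 s)
receives a broadband amplitude factor (default 1.3), reproducing the
direction that articulation drives stronger signals and stronger
sensor correlations than imagination.

Band-limited sources carry the spectrum of *zero-phase 4th-order
Butterworth band-passed white noise*.  They are synthesized in the
frequency domain: a Hermitian-symmetric complex Gaussian spectrum is
shaped by the filter's zero-phase magnitude response ($|H|^2$) and
inverse-transformed.  This is distributionally equivalent to filtering
white noise and keeps the generator and the analysis filter bank
self-consistent, while being fast enough to simulate hundreds of
full-length epochs on one CPU.  The shared-source construction makes
the expected pairwise correlation analytically tractable
($\rho^2 \sigma^2$ over the total channel variance), which the tests
use as an oracle.

Two presets define the study conditions: `"null"` makes both cohorts
generatively identical ($g_\beta = 1$, equal $\rho = 0.3$);
`"beta-effect"` sets $g_\beta = 1.5$ and patient $\rho = 0.6$ against
healthy $\rho = 0.3$.  Per-band source amplitudes decline with
frequency (1, 0.8, 0.7, 0.6, 0.4, 0.3 from delta to high gamma over a
unit pink background), a realistic 1/f-like profile.  The full
recording-scale layout (196 channels, 60 trials per phrase) is
available via
`scale = "full"`; the default *reduced scale* (32 channels, 20 trials
per phrase, 3+3 participants, 5 phrases, 1 kHz, −0.5..4.5 s) keeps a
full pipeline run tractable on a single CPU while preserving every
structural property the analyses rely on: the leave-one-pair-out fold
design, the 15-per-cohort summary samples (df = 28), and all four
qualitative cohort contrasts.

The effect sizes of the `"beta-effect"` preset are *not* estimates of
real patient data — no quantitative effect size is available for it —
they are chosen once so that all four analyses detect the effect at the
reduced scale.  Consequently, passing tests demonstrate that the
pipeline recovers planted effects of plausible structure, not that it
would reach any particular accuracy on recorded MEG.  Real recordings
additionally contain non-Gaussian artifacts, inter-channel leakage
fields, head-position differences and nonstationarities that the
generator deliberately does not model.  A per-participant amplitude
jitter parameter exists (`participant_jitter_sd`) but defaults to 0:
the channel model treats participants within a cohort as exchangeable,
and subject-level amplitude offsets would make held-out-pair
classification systematically deviate from the 50% chance level even
under the null — a leave-subject-out artifact worth studying, but not
part of the baseline conditions.

## Signal conditioning

The conditioning chain is fixed: zero-phase Butterworth low-pass
(250 Hz, 4th order) with integer-ratio decimation to 1 kHz → zero-phase
2nd-order IIR notch at 60 Hz and every harmonic below Nyquist →
segment parsing → channel exclusion and trial rejection.

* **Zero-phase application.** All filters run forward–backward, so
  effective orders double and group delay is zero; band-power windows
  are therefore not biased in time.  The implementation pads each
  signal by odd reflection (3× the coefficient length) and starts both
  passes from the steady-state filter state, the convention familiar
  from MATLAB's and scipy's `filtfilt`; with zero-padding instead, the
  notch's long impulse response (pole radius ≈ 0.99) would leak visible
  edge transients into the epochs.
* **Notch design.** A biquad with zeros on the unit circle at ±60 Hz
  and poles at radius $1 - \pi\,\mathrm{bw}/f_s$ (default bw = 3 Hz
  single-pass).  After the forward–backward pass the line frequency is
  down by > 60 dB while tones 5 Hz away lose < 1 dB.
* **Resampling.** The 250 Hz low-pass is the anti-alias guard; the
  decimation step requires an integer rate ratio (4 kHz → 1 kHz in the
  recording layout emulated here).  Arbitrary-ratio resampling is out
  of scope.
* **Trial rejection.** Visual artifact screening is replaced by a
  deterministic rule — drop trials whose peak absolute amplitude
  exceeds 5× the median trial peak — and the first 60 surviving trials
  per (participant, phrase) cell are kept, in original order.  An
  ICA-style cleanup is supported only as an externally supplied
  keep/drop mask (`apply_trial_mask()`); the decomposition itself is
  out of scope.
* **Bad channels.** The recording layout this emulates discards 8 of
  204 gradiometers (the same set for all participants); the exclusion
  list is an input, since no published label list exists.

## Spectral estimation

Band power uses Welch's method: 1 s Hann windows at 50% overlap,
mean-removed per window, one-sided density normalized so that its
integral approximates the signal variance.  The density is integrated
over each band with the trapezoidal rule (with linear interpolation at
off-grid band edges), giving mean power in linear signal units squared.
Welch was chosen over a raw periodogram because single-trial segments
of 1–2.5 s need variance stabilization; the estimator is a documented
choice, not a claim about the original analysis, which states only
"average power".  On a 1 s covert segment the delta band (1–4 Hz) spans
a single period of its lowest frequency; the estimate is accepted (the
band is part of the feature set) but is the least reliable of the six,
which is worth remembering when delta-band classification accuracies
look unstable.  Broadband features default to 1–119 Hz, matching the
span of the six bands; a 0.3–250 Hz variant is available through
`broadband_spec("wide")`.

## Connectivity estimation

AEC is computed without leakage orthogonalization — the analyses work
in sensor space, and the shared-source coupling the generator plants is
exactly the kind of common signal orthogonalization would remove.
Trial-averaged correlations average r directly, matching the
arithmetic-mean definition of the density statistics; Fisher-z
averaging is available behind a flag (`fisher_z`).  Envelope edges are
handled in two layers: each trial is odd-reflection extended by 250 ms
before filtering so the FFT Hilbert transform's circular-junction
artifact falls outside the analyzed window, and 100 ms of envelope is
trimmed at each end before correlating.  With both in place, keeping
versus dropping the trimmed edges moves AEC by well under 0.02 on
2.5 s trials — the estimator is not edge-dominated.

The "95% of correlation values" interval is operationalized as a seeded
bootstrap percentile interval of the pooled pair-correlation
distribution.  The original Bayesian/Monte-Carlo procedure is not
reconstructible from its one-line description; a bootstrap interval is
a transparent, deterministic substitute with the same interpretation.

## Statistics

Group tests always run on participant × phrase summary statistics,
never on trial-level values — pseudo-replication would overstate the
evidence.  The two-sample t is the pooled (Student) variant, matching
df = 28 at 15 + 15 samples; Welch's correction is deliberately not the
default because the pooled df is part of the design being reproduced.
The band comparison is a one-way ANOVA over six bands with the five
per-phrase mean distances as samples — df (5, 24) — followed by Tukey's
HSD at α = 0.05.  ANOVA and Tukey delegate to `stats::aov` and
`stats::TukeyHSD`; the tests cross-check the adjusted p-values against
the studentized-range formula directly.

## Classification

The regularized LDA discriminant is
$w = [(1-\gamma) S + \gamma\,\mathrm{diag}(S)]^{-1} (\mu_1 - \mu_0)$,
with weights $|w_j| \le \delta$ zeroed and the usual threshold from
class means and empirical priors.  At $\gamma = 1$ this reduces to
diagonal LDA, which the tests verify against the closed form.  Features
are standardized with training-fold statistics so that $\delta$ values
are comparable across bands and feature scales; this standardization is
fitted strictly inside each outer fold.

Hyperparameters are tuned by a seeded exhaustive grid
($\gamma \in \{0, 0.01, 0.1, 0.3, 0.5, 1\}$,
$\delta \in \{0, 10^{-4}, 10^{-3}, 10^{-2}\}$) under stratified 10-fold
cross-validation on the training data of each outer fold.  A Bayesian
optimizer would mirror the original tooling but is stochastic and
irreproducible across implementations; an exhaustive grid over the same
two parameters is deterministic and auditable.  Ties break toward
larger $\gamma$, then larger $\delta$ — when accuracies are equal,
prefer the more regularized model.  Grid points that fail to fit
(singular covariance at $\gamma = 0$ when features outnumber training
trials) are scored as failures and can never be selected.

The outer loop is leave-one-participant-pair-out: both members of a
(healthy, patient) pair are entirely unseen during training and tuning,
so fold accuracy measures subject-level generalization.  Chance level
for the balanced two-class test sets is 50%, which the null-preset
calibration asserts.  Note that full (γ = 0) LDA predictions are
invariant to feature scaling, but shrinkage toward the diagonal is
scale-sensitive — another reason features are standardized with
training-fold statistics.

## Numerical and design choices worth knowing

* **Epoch container.** A single-file binary container: magic string,
  schema version, JSON metadata header, raw little-endian doubles.
  Round trips are bit-exact; unknown extra header fields load with a
  warning; truncation and version mismatches are detected.  An HDF5
  layout was the natural alternative, but no R HDF5 interface is
  available in the supported dependency set, and a self-describing
  single file serves the same portability goal for this data volume.
* **Problem sizes.** The test suite exercises the reduced scale
  (32 channels, 20 trials/phrase): 20 null datasets for test
  calibration, 10 beta-effect datasets for the direction checks, and
  one full orchestrated run.  These sizes were chosen so the whole
  suite completes in tens of minutes on a single CPU; all design
  arithmetic (folds, df, channel counts) is additionally checked at
  full scale where it is cheap to do so.
* **Null-calibration path.** The rejection-rate calibration drives the
  analysis statistics directly on parsed segments without the low-pass
  and notch stages: conditioning is identical for both cohorts and
  cannot change a cohort-exchangeable null into a rejection, while
  skipping it keeps 20-seed calibration affordable.  The orchestrated
  `run_all()` path always applies the full conditioning chain.
* **Strong-pair counts** use a strict inequality (|r| > 0.5) and are
  reported both as pair counts and as per-sensor counts (sensors in at
  least one strong pair), since the source wording is ambiguous between
  the two readings.  On weakly coupled data all cells can be zero; the
  pipeline then reports the degenerate t-test as unavailable rather
  than failing.
* **Limitations.** Sensor-space only (no source mapping, by design);
  no orthogonalized AEC or phase metrics; no behavioral (audio/jaw)
  stream; the generator's Gaussian stationary sources understate real
  artifact structure; arbitrary-ratio resampling unsupported.
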