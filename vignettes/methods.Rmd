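---
title: "Models and methods behind pupilcb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pupilcb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pupilcb analyzes event-related pupillometry from choice-blindness
experiments: sessions in which a participant repeatedly chooses between two
stimuli and, on a minority of *manipulated* trials (M-trials), is shown the
non-chosen stimulus as if it were their choice. Participants often fail to
report the swap; the central question is whether unreported manipulations
were nevertheless *covertly detected*, which is probed behaviorally (a
retrospective memory task) and physiologically (pupil dilation, a standard
arousal/surprise marker). This vignette documents the models, the generative
assumptions of the synthetic cohorts, the numerical choices, and what the
test suite does and does not establish.

## Session structure

A session has 30 trials: 8 M-trials at fixed positions (7, 10, 14, 16, 20,
22, 26, 29), 8 non-manipulated trials (NM) at random positions, and 14
baseline trials (stimulus selection followed only by fixation and the test
image, with no report phase). Each M/NM trial runs pair presentation (3 s in
the color-photograph profile, 5 s in the monochrome-face profile), ratings,
2.5 s fixation, 5 s test image, the report window, and a 2 s intertrial
interval. The rating and report phases have no prescribed duration in the
protocol; the generator fixes both at 4 s so that test-image onsets are
deterministic and every run is exactly reproducible. All analysis windows
are locked to test-image onset.

## Synthetic cohorts

No quantitative generative model of reporting exists for this paradigm, so
the generator's behavioral parameters are loose calibrations, not estimates;
they are free parameters with documented defaults, chosen once.

**Behavior.** Each subject draws a reporting phenotype (all-report,
some-report, no-report) with weights 8/41, 23/41, 10/41 — the observed group
sizes. Detection of an M-trial is Bernoulli with logit
`b0 + b_trial (order - 4.5) + b_conf (conf - 5) + b_dissim 1[dissimilar]`
(defaults 1.4, 0.35, 0.25, 0.5): detection becomes more likely later in the
session, with higher choice confidence, and for dissimilar pairs, matching
the direction of the reported odds ratios. Concurrent report requires
detection — the generator never fabricates a false report — and its
probability is phenotype-dependent (0.98 for all-report, 0.02 for no-report,
logistic in M-trial order for some-report). A detected but unreported trial
is coded as a vague "possible detection" with probability 0.02.
Retrospective report is Bernoulli given detection with logit
`1.5 + m_mem`, where the memorability offset `m_mem` is +1.0 for the
color-photograph profile and -1.5 for the monochrome-face profile (these
stimuli are much harder to remember); false positives on non-manipulated
pairs occur at 0.033 and 0.087 per pair respectively, the observed
false-alarm rates.

**Pupil traces.** A 1000 Hz trace is baseline + drift + event-related
responses + saccade transients + white noise, in arbitrary device units.
The event-related response of a trial is an impulse train convolved with
the canonical pupil impulse response (below). The defaults place one
impulse per second of the 5 s test image (offsets 0..4 s): a single
impulse at onset would have decayed almost completely by 2 s, whereas the
paradigm's detection response is sustained through the 2-4 s analysis
window, which is exactly where the window statistics look. Setting
`response_offsets_s = 0` recovers the single-impulse configuration used by
the noise-free reconstruction tests. Impulse amplitude is `amp_base = 20`
for every trial, plus `amp_delta_detect = 15` on truly detected M-trials;
truly undetected M-trials add `amp_delta_undetect = 0` by default, so any
covert-detection signature in synthetic data comes from
detected-but-unreported trials, not from an artifact of the generator.
With session SDs around 11-15 a.u. this puts the detected-trial window
effect near 0.6-0.9 z, the order of magnitude reported for real data.
Two per-subject multiplicative gains — one on response amplitudes (SD
0.25) and one on the noise and drift scales (SD 0.3) — create
between-subject heterogeneity in z-scored response size; an amplitude gain
alone would mostly cancel under session-SD standardization. Under the
defaults this yields intraclass correlations around 0.10-0.15 in
trial-level window models, the right order of magnitude for repeated
pupillometry. Both gains are recorded implicitly in the ground truth's
per-trial injected amplitudes, so recovery tests remain exact.
Blinks arrive as a Poisson process (0.25 Hz; lognormal durations, median
~120 ms), zero the pupil with 50 ms cosine ramps, are flagged invalid, and
leave an IRF-shaped recovery transient (amplitude 5 a.u.) at blink end —
the component nuisance regression is meant to remove. Saccades (1.5 Hz)
inject a small biphasic transient (0.1 × noise SD). Drift is a Wiener
process (5 a.u./√s); everything below 0.02 Hz is removed by the band-pass
anyway, so its exact spectrum is immaterial.

**What the generator does not emulate:** gaze-position-dependent pupil
foreshortening, luminance responses, slow vigilance cycles, non-stationary
blink rates, or any dependence of pupil dilation on *reporting* (as opposed
to detection). Passing recovery tests on these cohorts therefore shows the
pipeline is correct under its stated model, not that the model captures
every property of real eye-tracker data.

## Preprocessing

The chain is fixed: interpolate → band-pass → z-score → downsample →
nuisance regression → epoch → QC; every stage stamps a provenance tag and
refuses out-of-order input.

* **Interpolation.** Blink and missing-data intervals, padded by 150 ms on
  both sides, are replaced by linear interpolation between the nearest
  valid samples; edge gaps extend the nearest valid value. Replaced samples
  stay flagged invalid — filled, not trusted.
* **Filtering.** Zero-phase (forward-backward) third-order Butterworth
  band-pass, 0.02-4 Hz. Numerically this is a cascade of third-order
  high-pass and low-pass sections: the single sixth-order transfer
  function is unstable in double precision at a 1000 Hz rate with a
  0.02 Hz corner, while the cascade is exact to ~1e-3 against the analytic
  magnitude response. `filtfilt` starts from zero filter state, so the
  signal is demeaned first and padded by 60 s of anti-symmetric reflection
  (several times the ~8 s time constant of the low corner); residual edge
  transients are below 1e-3 of the DC step. Zero-phase filtering is chosen
  so epochs suffer no latency shift.
* **Standardization.** The protocol's "z-scored to the pre-stimulus
  baseline" is ambiguous between per-trial and session-level scaling. A
  per-trial z over the 100 baseline samples is unstable (its SD estimate
  has ~14% relative error and would inflate variance heterogeneously), so
  the signal is divided by the session SD of valid filtered samples, and
  the per-trial baseline *mean* over [-1, 0) s is subtracted at epoching.
  Baseline-relative comparisons are unaffected by this reading. The
  session scale is retained so effects can be mapped back to device units.
* **Downsampling.** Decimation 1000 → 100 Hz (the 4 Hz low-pass already
  provides the anti-alias margin); a decimated sample is invalid if any
  native sample in its block was.
* **Nuisance regression.** One regressor per event kind: a unit impulse at
  each event *end* (the recovery onset; the protocol does not state onset
  vs end, and end-locking is the simpler reading for blinks, whose
  artifact outlasts the event) convolved with the canonical pupil
  response, plus an intercept; OLS over valid samples; the residual is the
  cleaned signal.
* **Canonical IRF.** `h(t) = t^w exp(-w t / t_max)` with `w = 10.1`,
  `t_max = 0.930 s`, unit peak, 4 s support — the standard parameterization
  of the pupillary response to brief events; both constants are
  configurable.
* **Epoching and QC.** Epochs span -1..5 s at 100 Hz (601 samples; t = 0 at
  index 100, 0-based). A trial is excluded iff *strictly more than* one
  third of its native-rate window samples are invalid (exactly 2 s of 6 s
  is retained, 2001 ms is not). The protocol's subject rule — "more than
  half of invalid trials (15 out of 30)" — is self-contradictory at the
  boundary; the parenthetical wins: a subject is excluded at ≥ 15 excluded
  trials. Both thresholds are configuration fields.

## Statistics

* **Pointwise tests.** Trials are averaged per subject per condition first;
  each time point on 0..5 s (501 points) gets a paired t-test, one-sided
  for the directional contrasts (detection should *increase* pupil size).
  Benjamini-Hochberg FDR at q = 0.05 is applied within one contrast's 501
  points — the protocol is silent on the family definition, and pooling
  across contrasts would couple unrelated hypotheses. When nothing
  survives FDR an uncorrected α = 0.05 mask is reported as exploratory.
* **Window statistics.** Trial-level means over 2-4 s; subject-level group
  means normalized by *subtracting* the subject's baseline-trial mean
  (a ratio would distort conditions that fall below baseline, which NM
  trials demonstrably can). The battery: each M group (all M, concurrent
  report, no concurrent report, retrospective-only, no report) vs baseline
  and vs NM one-sided, group pairs two-sided, raw p per comparison (the
  protocol reports no correction across the battery). Comparisons with
  fewer than two paired subjects are flagged not-estimable rather than
  dropped silently.
* **Mixed models.** Reporting: logistic with trial order, confidence and
  similarity fixed, participant random intercept, Laplace ML; odds ratios
  with Wald 95% CIs (the CI method behind the published intervals is not
  stated; Wald is the default and profile CIs can be obtained from the
  returned fit). Constant outcomes are flagged as separation, not fit.
  Pupil size: linear mixed models on trial-level window means, REML by
  default (also not stated in the protocol; REML is the conventional
  choice for variance components, and the ICC is the target quantity),
  ICC = σ²_subj / (σ²_subj + σ²_resid), singular fits flagged.
* **Classification.** Leave-one-subject-out midpoint threshold: the
  held-out subject's trials are classified against the midpoint of the two
  class means from all other subjects' *pooled* trials (the stated
  "mean response values ... from all other participants"; a
  mean-of-subject-means variant is available). Ties go to the reference
  class, conservative toward chance. Accuracy is tested with an exact
  one-sided binomial tail against the majority class proportion computed
  on the full included-trial set; sidedness of the published test is not
  stated, and the upper tail is the reading under which "above chance" is
  meaningful.
* **Power.** Paired differences are drawn from Normal(d, 1) so d is
  exactly the paired Cohen's d; the one-sample t-test at α is applied per
  replicate; 20,000 replicates give a Monte-Carlo SE below 0.4 percentage
  points. Every simulated cell is cross-checked against the noncentral-t
  closed form (df = n-1, ncp = d√n).

## Numerical choices and degenerate inputs

Event intervals are half-open `[start_ms, end_ms)`; a sample at time t
belongs to an event iff `start_ms ≤ 1000 t < end_ms`. Missing pupil data is
an invalid-mask state, never NaN past interpolation. A paired contrast with
zero-variance zero-mean differences reports t = 0, p = 0.5 one-sided
(identical conditions are evidence of nothing, not an error). d′ on a hit
or false-alarm rate of 0 or 1 is infinite; the log-linear correction
(+0.5 per cell) is applied only when a rate is extreme, and per-subject d′
(where extremes are common) uses it by default. Printed percentages round
half-up at the published number of decimals. κ with both raters constant
and identical is undefined and flagged. Sixty-second filter padding,
demeaning before filtering, and the high-pass/low-pass cascade are the
three numerical guards around `filtfilt`; all were verified against the
analytic Butterworth response.

## Problem sizes in the test suite

Property tests run at sizes chosen for statistical resolution: 200-subject
cohorts for parameter recovery (window-contrast amplitude against an
independently coded trace oracle at a 99% Monte-Carlo CI; trial-order odds
ratio 1.9; ICC 0.25), 1000 simulated null cohorts for the FDR
any-discovery rate (threshold 0.05 plus a 0.025 Monte-Carlo allowance,
fixed in advance), 400/250 replicates for LMM/GLMM CI coverage with bands
widened by the corresponding binomial Monte-Carlo error, and 20,000
replicates per power cell. The full-pipeline recovery deliberately keeps
the generator's defaults — including blinks, saccades and drift — rather
than a sanitized configuration.

## Known limitations

The pipeline consumes already-coded report labels; it does not parse
transcripts (the κ routine only scores two coders' label vectors). ASC
parsing is a minimal adapter for sample and blink/saccade lines, not a full
EDF/ASC reader. Nuisance regression uses a fixed canonical kernel, not
subject-specific deconvolution. The published pupil coefficients, d′ values
and classification accuracies from the real dataset are not reproducible
without that dataset; the suite replaces them with parameter-recovery and
oracle-equivalence checks on synthetic cohorts, which is a weaker but
honest guarantee.
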