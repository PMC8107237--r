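---
title: "Blind visualization of task-related networks from EEG-fMRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blind visualization of task-related networks from EEG-fMRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the four fusion models

Simultaneous EEG-fMRI records fast electrophysiology and slow
hemodynamics of the same brain at once. `specfuse` implements a fully
automated ("blind") fusion strategy: instead of building fMRI
regressors from known stimulus timings, it derives them from
fluctuations of the EEG power spectrum itself, so task-related networks
emerge without the analysis ever seeing the event schedule.

The EEG of each subject, session and lead is z-scored, cut into
epochs of one repetition time (TR = 1.66 s by default, locking one
epoch to one fMRI scan), and Fourier transformed. Squared coefficient
moduli give *absolute* power; dividing each bin by the epoch-channel's
total power over all bins gives *relative* power. Stacked over epochs,
channels and the 0-40 Hz bins this forms the spatiospectral matrix
`E(n_t, n_c, n_omega)` — with the default acquisition geometry,
67 bins per epoch and channel.

A pattern is a fixed weighting of this spectrum whose scalar
fluctuation over epochs drives the BOLD signal. Four models differ in
how the weighting is obtained and which power type it weights:

* **ASM / RSM** (absolute / relative spectral model): a spectral filter
  `g(omega)`, applied per channel, z-scored over time and averaged over
  leads.
* **ASSM / RSSM** (absolute / relative spatiospectral model): a full
  channel-by-frequency pattern `g(c, omega)` obtained by group ICA of
  `E`; its per-epoch mixing weight is the fluctuation.

The decomposition model is `E = W S`: two-stage PCA (per
subject-session to 50 temporal components, then group-wise to 20)
followed by Infomax ICA with 10 stability runs. The spectral filters of
ASM/RSM are the lead averages of the spatiospectral patterns, so all
four models share one pattern dictionary. Per-subject dynamics are
recovered by back-reconstruction: the unit's partition of the temporal
PCA basis times its partition of the group basis times the mixing
matrix.

Task relatedness is assessed per subject by ordinary least squares of
the pattern fluctuations on a binary epoch design (one column per
stimulus type and session plus one DC column per session; 16 columns
for three types and four sessions), followed by a group one-sample
t-statistic `t = sqrt(s) * mean / sd` of the summed stimulus-type
coefficients over subjects. A pattern-type pair is *task-related* when
any model's |t| exceeds the Bonferroni threshold (3.25 for ten
comparisons at 16 degrees of freedom, kept as the fixed default), and a
*candidate* when the across-model mean |t| exceeds 2.0 with an
across-model standard deviation (population form, denominator = number
of models — the form that reproduces the published example rows) below
0.5.

Fusion regresses every voxel's BOLD series on the selected pattern's
fluctuation convolved with a canonical double-gamma response (peak
delay 6 s, undershoot delay 16 s, unit dispersions, 1:6
peak:undershoot ratio, peak-normalized, 32 s support) *and its first
two temporal derivatives*, so response amplitude and latency may vary
voxel by voxel. Group inference is a one-way ANOVA F over the three
coefficient maps of `s` subjects, `F(3, 3s - 3)`, testing all three
group means jointly against zero. Each voxel's group-mean response
`h = b1 r + b2 r' + b3 r''` is reconstructed, and voxels whose trough
amplitude exceeds their peak amplitude carry a negative sign on the
F-map. Suprathreshold clusters (default `F >= 5.7`, at least 100
voxels, 18-connectivity) are summarized by volume, mean, median and
maximum |F|.

## The synthetic oddball study

The generator emulates a three-stimulus visual oddball experiment:
70% frequents, 15% targets, 15% distractors at inter-stimulus
intervals drawn uniformly from 4/5/6 s, 84 stimuli in each of four
sessions of 256 scans (TR 1.66 s), eight subjects, 30 EEG leads at
250 Hz, and a desk-scale 20 x 20 x 10 voxel BOLD grid at 3 mm. Type
counts are fixed by largest-remainder rounding, so every session
carries exactly the configured mix; ISI sequences that would overrun
the session are redrawn under the same seed.

Each ground-truth pattern is a band-limited rhythm with a fixed scalp
topography. Its amplitude envelope is a baseline plus, for each
stimulus, a one-epoch boxcar scaled by the type-specific modulation
amplitude, times a slow log-normal amplitude modulation (sd 0.5,
correlation time 8 s) that emulates the waxing and waning of real
rhythms. Sources are synthesized per epoch as random-phase multisines
whose magnitude spectrum follows the band-pass power profile (a
4th-order Butterworth magnitude response applied forward and
backward). This choice is deliberate: stationary filtered noise has
exponentially distributed per-bin epoch power, which makes every
frequency bin an independent source in its own right — the epoch
spectra then genuinely do not contain stable band patterns, and no
decomposition could (or should) find them. Profile-shaped epochs
realize the `E = W S` structure the method is built to detect; an
optional per-bin magnitude jitter (`bin_cv`) reintroduces bin-level
sampling noise for robustness experiments.

The default study embeds two patterns: a delta-band (1-4 Hz) pattern
whose envelope drops by 0.3 during frequent stimuli (about a 50% power
decrease, in the range of published event-related desynchronization
magnitudes) and an unmodulated alpha-band (8-12 Hz) background rhythm
as specificity control. Topographies are focal Gaussian bumps on the
channel axis — scalp rhythms are focal, and spaced bumps emulate
distinct generators. Each pattern couples to a disjoint 6 x 6 x 4
voxel block whose per-voxel response coefficients are drawn uniformly
(b1 in [0.6, 1.4], b2 in [-0.5, 0.5], b3 in [-0.3, 0.3]), so active
voxels span canonical through trough-dominant response shapes. BOLD
series add a per-voxel linear drift and stationary AR(1) noise
(coefficient 0.3); the noise scale is set from the session's median
active-voxel signal SD so that the contrast-to-noise ratio is 1 by
default. The recorded ground-truth fluctuation of a pattern is the
realized epoch mean-square amplitude of its modulated source — the
quantity the epoch spectra measure — not the deterministic envelope.

What the generator does *not* emulate: MR gradient or
ballistocardiogram artifacts, eye blinks, head motion, 1/f background
spectra, volume conduction from a head model, or spatially correlated
BOLD noise. Passing tests therefore demonstrate correctness of the
algorithms under the model's own assumptions, not robustness to real
recording artifacts.

## Numerical choices

* **FFT scaling.** Spectral coefficients are `fft(x) / sqrt(N)`, so
  summed squared moduli over all bins equal the summed squared time
  samples (Parseval); the DC bin is retained, which is what makes a
  1.66 s epoch at 250 Hz yield exactly 67 bins up to 40 Hz.
* **Relative power** divides by the total over *all* FFT bins of the
  epoch-channel (the Parseval-equivalent of time-domain energy), not
  only the retained band.
* **Variance conventions.** Channel z-scoring and the per-channel
  z-scoring inside the spectral models use the population form
  (denominator n); the group t uses the sample form (denominator
  s - 1). Constant channels raise errors rather than silently
  contributing zeros.
* **Infomax** is full-batch natural-gradient ICA with the logistic
  nonlinearity on whitened group data, learning rate 0.2 annealed by
  10% only when successive updates turn by more than 60 degrees.
  Convergence requires both a relative weight change below 1e-6 and a
  small natural-gradient norm, so a shrinking step cannot masquerade
  as a fixed point. Runs restart with a halved rate on numerical
  blow-up. The stability stage is a simplified ICASSO: greedy
  run-matching by absolute source correlation, centrotype
  representatives, mean within-cluster |r| as the stability index.
* **Unit PCA is centered over time** (feature means are kept and
  restored on reconstruction), the standard group-ICA practice; with a
  complete unit basis and the true rank, reconstruction of the unit
  data is exact.
* **Stable-pattern pool.** Patterns must match across the absolute and
  relative decompositions (|r| >= 0.7), be run-stable (index >= 0.8),
  *and* carry an above-average share of retained variance. The last,
  Kaiser-style gate exists because deliberately overfactored
  decompositions (m = 20 with few true sources) produce deterministic
  low-variance residue components that replicate perfectly across
  runs — run-to-run stability alone cannot reject them.
* **Convolution** happens on a fine grid whose step divides the TR
  (default TR/20); each epoch value enters as an impulse at its epoch
  onset, so a unit impulse reproduces the basis functions exactly at
  scan times. Regressors are mean-centered per session; session DC
  columns carry the intercepts; no orthogonalization among the three
  basis regressors. Note that a constant fluctuation yields constant
  regressors only after the causal convolution has ramped past the
  basis support.
* **Estimation** defaults to voxelwise OLS; two-pass AR(1)
  prewhitening with a pooled lag-one autocorrelation approximates
  restricted maximum likelihood at a fraction of the cost.
* **Thresholds.** The published critical values (t 3.25; F 5.7, 8.1,
  12.1; 100-voxel extent) are fixed defaults rather than derived
  quantities — the F thresholds cannot be reproduced from the stated
  degrees of freedom, so they are treated as conventions of the
  original analysis. `critical_t()` provides the analytic Bonferroni
  alternative.
* **Clusters** use 18-connectivity by default (6 and 26 available);
  a voxel exactly at the threshold is included; volumes are exact
  multiples of the voxel volume taken from the image geometry.

## Problem sizes used by the test suite

Routine tests run on a miniature study (2-3 subjects, two sessions of
128 scans, 10 channels, a 12 x 12 x 8 grid). The end-to-end
blind-detection experiment runs twenty replicates of the oddball study
at its full acquisition size (eight subjects, four sessions of 256
scans, 30 channels) with a reduced decomposition order — ten group
components over 30 unit PCs — the package's choice for a quick
default suite; selection statistics and fusion maps behave the same at the
twenty-component order, which was verified interactively during
development. The relative spectral model needs the full four sessions
to localize reliably: on two-session studies its (weakest) maps peak
at noise in roughly a fifth of replicates, consistent with its rank as
the least robust of the four models.

## Known limitations and an honest finding

* **Spectral-model crosstalk.** The ASM applies one spectral filter to
  every lead and averages z-scored channel courses. Channels that do
  not carry the filtered rhythm contribute amplified noise — and any
  leakage of a strong task rhythm into the filter's passband — to the
  average. With a strongly modulated delta pattern present, the
  unmodulated alpha pattern's ASM fluctuation can acquire a detectable
  task coupling through residual ICA contamination.
* **Relative-power compensation.** Relative normalization makes every
  band's share rise when total power falls. A frequent-stimulus drop
  in delta power therefore induces a genuine *positive* frequent
  response in the relative-power fluctuation of an unmodulated alpha
  rhythm on delta-carrying channels. In the default study the RSM
  flags the background pattern with |t| around 20 — not a false
  positive in the statistical sense, but an induced coupling inherent
  to relative power. Consequently, "exactly one pattern flagged" is
  not attainable with the spectral models when a background rhythm
  shares channels with broadband power changes; the spatiospectral
  models (ASSM/RSSM) remain clean (null |t| < 1 in the same studies).
  This mirrors the original observation that relative power amplifies
  frequent-stimulus relationships across bands.
* **Overfactoring dilutes signatures.** With m components well above
  the true source count, recovered pattern signatures absorb
  noise-subspace structure (correlation with truth drops from > 0.99
  at the true rank to about 0.7-0.9 at m = 20 on two-source studies),
  while back-reconstructed *dynamics* remain essentially exact. The
  variance-share gate keeps the pattern pool clean regardless.
* The group F assumes independent observations across the three
  coefficient maps; correlated basis regressors make it approximate
  (the null calibration test uses independent coefficients, matching
  the test's own assumptions).
* Selection by the published OR rule is not monotone in |t|: raising
  one model's |t| can push the across-model SD over its cap and
  un-select a candidate pair. Only the family-wise rule is monotone.
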