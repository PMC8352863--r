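---
title: "Quantifying button-press-related sensorimotor desynchronization during sitting and walking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying button-press-related sensorimotor desynchronization during sitting and walking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobersp)
```

## The model of the data

`mobersp` analyzes independent-component (IC) activations epoched around
visual stimuli that require a button press. The signal model behind both
the analysis and the synthetic generator is

* a broadband aperiodic background whose one-sided spectral density
  follows a power law, `P(f) = 10^b · f^(−χ)`, with offset `b` (log10
  power at 1 Hz) and exponent `χ`;
* band-limited oscillations near 10 Hz (alpha) and 21 Hz (beta) riding
  on that background; and
* a movement-related suppression of the oscillation amplitudes around
  the button press — event-related desynchronization (ERD).

The generator plants the ERD as a multiplicative Gaussian envelope on
each band carrier, `1 − d·exp(−(t − t₀)²/(2σ²))`, with `t₀` placed
relative to each trial's response time. The power ratio at the trough is
then exactly `(1 − d)²`, which gives every recovery test an analytically
known target: a half-power suppression corresponds to
`10·log10(0.5) ≈ −3.01` dB.

## Time-frequency decomposition and warping

Single-trial spectrograms use complex Morlet wavelets on 37 log-spaced
frequencies from 4 to 40 Hz. The cycle count expands linearly in grid
index from 3 at 4 Hz to 15 at 40 Hz; the published description of the
cycle rule ("linear 0.5 increase") is ambiguous, but both endpoints are
stated and fully pin down a linear rule, which is what
`make_freq_grid()` implements. Samples closer to an epoch edge than the
wavelet half-length are marked invalid and excluded from every
downstream average; a time-frequency cell enters a condition map only
where *all* trials are valid, because cells covered by a shrinking trial
subset otherwise inherit the variance of a handful of trials.

Trials are warped to a common stimulus-response interval (response at
356 ms, the mean response latency of the emulated study) by
piecewise-linear remapping with anchors at the epoch limits, stimulus
onset, and the response. The warp is applied to the time-frequency
representation, not the raw signal, matching the stated order of
operations of the emulated analysis; power values are linearly
interpolated.

Normalization follows the full-epoch single-trial scheme: each trial is
divided, per frequency, by its own full-epoch mean. Condition maps are
trial means, dB-transformed and referenced to the −300:−100 ms
pre-response baseline per frequency. The final map is interpolated onto
a 1 ms grid so that the ±20 ms suppression-extraction window spans
exactly 41 samples.

Internally the wavelet transform is evaluated at a 4-sample hop
(16 ms at the 250 Hz default rate). The shortest wavelet time constant
on the grid is ~60 ms, so power envelopes contain no structure between
hop points; the 1 ms output grid is reconstructed by interpolation.
`wavelet_power(..., hop = 1)` disables the stride, and the test suite
verifies the full-resolution transform against a direct time-domain
convolution oracle to better than 1e−6 relative error.

## Repetitive ROI-targeted clustering

ICs are clustered on their equivalent-dipole location (weight 10) and a
coarse ERSP summary (weight 3). Each measure is standardized across ICs
before weighting — weights are meaningless across heterogeneous units
otherwise — then concatenated and compressed to the first 10 principal
components. The ERSP summary is deliberately low-dimensional (a 2 × 3
band-by-time block mean by default): with a high-dimensional summary the
many weight-3 columns would dominate the three weight-10 dipole columns
in total variance, inverting the intent of the weighting.

Each k-means solution (k = 14, three restarts) relabels ICs whose
centroid distance z-score within their cluster exceeds 3 as outliers.
The procedure repeats 10,000 times (configurable; scaled runs use
30–200 repetitions) with derived seeds. Within each repetition the
candidate cluster is the one nearest the target ROI — left
(−33, −10, 49) or right (38, −7, 48) Talairach motor coordinates, with
negative x as the left hemisphere. Across repetitions six metrics are
z-scored and combined with weights +3 (participants), −2 (ICs per
participant), −1 (dipole spread, mean residual variance, ROI distance,
Mahalanobis distance to the median candidate); the highest score wins,
with ties broken by ROI distance and then repetition order. The
Mahalanobis term is computed over the five base metrics relative to the
median candidate — it cannot include itself — and degenerates gracefully
(zero contribution, with a warning) when a metric has no variance across
repetitions.

## Spectral parameterization

Welch PSDs use 2 s Hann windows with 50% overlap inside epochs — the
emulated study states only that spectra came from FFTs, and Welch
averaging is the stable desk-scale choice. The aperiodic component is
fit without a knee on 2–40 Hz: a robust line fit in log-log space
(bins far above the line are dropped once and the line refit), iterative
Gaussian peak extraction in the flattened spectrum (threshold 2 SD of
the flattened residuals with a 0.05 log10-unit floor, at most 6 peaks,
bandwidth 1–12 Hz), then a final line fit on the peak-removed spectrum.
Band peak power is the raw log10 power at the local maximum of the
corrected spectrum inside the band; a band without a local maximum at
least 0.05 log10 units above the background yields the band mean with a
`no_peak` flag, which propagates rather than being imputed.

## Desynchronization measures and costs

Extraction is data-driven: the grand-average map over all participants
and contrast conditions fixes the per-band suppression latency; each
participant's individual maximum is searched within ±100 ms of it; the
reported measure is the mean dB over ±20 ms and ±1 (alpha) or ±2 (beta)
neighboring log-spaced bins around the individual maximum. The
neighbor rule is read as grid bins because Hz-symmetric windows do not
exist on a log-spaced grid; averaging sets are truncated at the grid
edge with a warning. Averages are taken on the dB scale, the literal
reading of the emulated procedure. Dual-task costs use the proportional
formula `(single − dual)/single · 100` with sitting as the single task,
and the cost–speed analysis also reports a combined (mean of alpha and
beta) cost, the direct counterpart of the planted coupling.

## Statistics

The 2×2 mixed ANOVA uses `aov` with a subject error stratum; generalized
eta squared is computed as effect SS over effect SS plus all error SS
(Olejnik–Algina with subject as the only observed factor). An
independent closed-form sums-of-squares oracle in the test suite checks
F, p, and η²g to 1e−8. Skewed cost distributions are ordered-quantile
normalized, `Φ⁻¹((rank − 0.5)/n)`, before Welch t-tests. Partial
Spearman correlations rank-transform all variables and partial out age
group (the study design provides group, not continuous age) with
`df = n − 3`; FDR adjustment is Benjamini–Hochberg within each family
(cost t-tests; correlation table).

## The synthetic cohort: what it emulates, and what it does not

Defaults encode the emulated study design: two age groups of 15, three
motor conditions, 100 stimuli per eccentricity (3 angles × 2 hemifields)
per condition — 1800 events — 2.5 s epochs from −1000 ms, 250 Hz
analysis rate, truncated-normal response times (mean 356 ms, SD 80 ms,
bounds 100–1000 ms; only the grand mean is reported, the rest is
convention). The standing condition is generated but excluded from the
default statistical contrast, mirroring the emulated focus on sitting
vs walking. Carrier frequencies are jittered per participant (SD 1 Hz
alpha, 2 Hz beta around 10.5/21 Hz) to exercise individual peak
detection.

Planted condition/group structure points in the reported directions:
deeper beta suppression and a higher beta power baseline in the older
group, deeper suppression in both bands while sitting, a higher
aperiodic offset while walking (−0.98 sitting vs −0.86 walking), no
exponent effects, and walking-speed dual-task costs negatively coupled
to desynchronization dual-task costs. Two calibration points matter:

* **Smoothing compensation.** The wavelet's temporal smoothing
  (σ_t ≈ 88 ms at 21 Hz) and the unsuppressed 1/f background both
  shallow a measured trough relative to the planted `(1 − d)²`; the
  compression factor is ≈ 0.6 at the default carrier-to-background
  ratios. Planted cell means are therefore set deeper than the target
  *measured* means, so that the recovered group/condition means land on
  the emulated study's printed values (beta: old ≈ −2.97, young ≈
  −1.57, sitting ≈ −2.83, walking ≈ −1.71 dB; alpha: sitting ≈ −2.20,
  walking ≈ −1.07 dB). The ERD-calibration test instead uses a broad
  (σ = 275 ms) envelope and a strong carrier so the smoothing bias is
  small against its ±0.5 dB tolerance.
* **Dispersion.** Between-participant intercepts (0.5 dB) and
  per-condition idiosyncratic variation (0.6 dB) are chosen so planted
  effects are detectable at the reduced cohort sizes used in examples
  and validation replicates, while total cell SDs stay below the
  printed observed SDs (≈ 1.0–1.65 dB) — the generator is, if anything,
  conservative about noise sources it does not model.

The generator does **not** emulate scalp-level volume conduction, ocular
or muscle artifacts, gait-cycle periodicity, non-stationary carrier
amplitude (carriers are fixed-amplitude sinusoids within a trial, so
trial-to-trial power variance is lower than in real EEG), or
eccentricity-dependent stimulus effects. Passing validation therefore
demonstrates that the analysis chain is correct and recovers known
structure of this class — not that it is robust to artifacts or
non-sinusoidal rhythms in real recordings.

## Numerical choices and degenerate inputs

* Wavelets are truncated at ±3.5 σ_t and convolved circularly with the
  kernel center wrapped to the origin; circular wrap-around only
  touches the masked edge margin.
* 1/f noise is synthesized by frequency-domain shaping of white
  Gaussian noise, giving exactly controllable offset and exponent.
* Warp rejects trials with a response outside (0, epoch end) with a
  warning; normalization rejects trials with non-positive full-epoch
  mean; an empty baseline window is an error.
* Tie-breaks: suppression argmin ties resolve to the earliest time and
  then the lowest frequency; clustering score ties to the smallest ROI
  distance, then the lowest repetition index.
* All randomness flows from explicit seeds through a deterministic
  sub-seed derivation; a pipeline run is byte-reproducible from its
  manifest.

## Scaled problem sizes

Full-size runs (15/group, 100 trials per cell, 10,000 repetitions) are
supported but unnecessary for validation. The package's validation uses
reduced sizes chosen as the smallest that keep all planted effects
clearly detectable: replicate cohorts of 8 per group with 48 trials per
condition and 3 ICs per participant; 200 clustering repetitions for
ROI-recovery checks; 200 generator-level replicates for the null
rejection rate. The statistics-layer type-I property is evaluated on
the generator's planted participant-level measures directly — the
wavelet chain contributes no hypothesis-level randomness of its own,
and the property under test is the test procedure's calibration.

## Known limitations

* The ±20 ms/±n-bin averaging on the dB scale differs from averaging
  linear power; the dB reading is implemented, and switching would
  change absolute values slightly.
* Latency recovery of the suppression maximum by argmin is noisy on
  shallow troughs; depth recovery is the calibrated quantity.
* With a single planted midline source, the left and right cluster
  solutions can legitimately overlap; the bilateral runner reports the
  overlap and warns rather than failing.
* Aperiodic fits assume no spectral knee in 2–40 Hz, by design; spectra
  with a knee in-range will bias offset and exponent.
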