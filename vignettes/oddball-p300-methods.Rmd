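---
title: "Simulating and analyzing visual-oddball P300 cohorts"
author: "oddballp300"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing visual-oddball P300 cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(oddballp300)
```

## The analysis this package implements

In a visual oddball session a participant watches a stream of frequent
standard flashes interrupted by rare, brighter target flashes, silently
counting the targets. Each stimulus evokes an event-related potential
(ERP); the P300 is its large positive deflection 300–600 ms after
stimulus onset, strongest over the midline. Two numbers summarize it per
subject, condition and electrode: the maximum peak amplitude (µV) and
its latency (ms). The clinical question driving the design is whether
target processing is slowed in mild cognitive impairment (MCI): the
group-level analysis is a 2 (group: HC/MCI) × 2 (condition:
target/non-target) × 3 (electrode: Fz/Cz/Pz) mixed ANOVA on the peak
measures, followed by simple-effect post-hocs and FDR-corrected
correlations between the peak measures and neuropsychological scores.

Because no raw recordings are publicly available, the package pairs the
analysis chain with a generator that produces cohorts with exactly the
statistical structure the analysis assumes, with ground truth attached.
Everything downstream (filters, ICA, rejection, measurement, statistics)
is agnostic about where the recording came from; `read_brainvision()`
ingests real BrainVision triplets in the same way.

## The generative model

A session is 120 stimuli, 40 of them targets (`round(120 × 0.33)`; a
`bernoulli_targets` flag switches to per-trial draws), in seeded shuffled
order with inter-stimulus intervals uniform on 3–7 s — roughly 10 minutes
at 500 Hz. Channels are Fz, Cz, Pz and one EOG channel.

Per subject and channel the rendered EEG is the sum of:

* **1/f background noise**, sd `background_noise_sd` (default 4 µV). The
  default puts the residual noise of a ~38-epoch average near 0.5 µV,
  which is what clean clinical subject averages look like.
* a **10 Hz alpha sinusoid**, amplitude `alpha_power` (default 1.5 µV),
  random phase per channel;
* one **P300 template per stimulus**: a positive Gaussian bump with
  condition- and channel-specific peak latency and amplitude and FWHM
  `width_ms` (default 120 ms, mid-range for P300). The Gaussian is the
  minimal single-component shape the peak measurements consume; the
  renderer takes any latency/amplitude cell matrix, so the shape is a
  deliberate simplification, not a claim about waveform morphology;
* **blink transients**: Poisson-timed (default 6/min) ~300 ms biphasic
  waveforms, 250 µV on EOG and propagated to Fz/Cz/Pz with weights
  0.4/0.2/0.08. This puts frontal blink artifacts in the 40–100 µV range
  of real recordings — large enough that they must be removed rather than
  merely rejected.

Group structure: each subject draws latent latency and amplitude factors
`z ~ N(0,1)`; cell values are `mean + sd·(ρ·z + √(1−ρ²)·ε)` with
`within_subject_corr` ρ = 0.8, using the published group × condition ×
channel means and sds as calibration cells (`p300_reference()`).
Latencies are clamped to 250–700 ms and amplitudes floored at 0.5 µV
(both events are rare at the calibrated cells, so the clamp's bias is
negligible). Neuropsychological scores use the published group marginals
(`neuropsych_reference()`) and couple to the latent factors through a
single-factor Gaussian copula: score `i` loads `c_lat` on the latency
factor and `c_amp` on the amplitude factor (feasibility
`c_lat² + c_amp² ≤ 1` is validated, and the factor construction keeps the
implied correlation matrix positive semi-definite by construction). Note
that a score coupled at `c` to the latency factor correlates with any
single measured cell at about `c × ρ`, not `c`. Score-specific rounding
and caps are applied afterwards (MMSE ≤ 30, recognition and Boston
naming ≤ 15, integer tests rounded), which attenuates extreme couplings
slightly. The reported target count is the true count plus a rounded
normal error whose mean and sd differ by group, matching the published
behavioral accuracy summaries. The depression-scale exclusion (GDS > 11)
is *not* enforced by default — the published MCI GDS spread implies such
scores existed in the analyzed sample — but `enforce_gds_cutoff = TRUE`
resamples them.

A single master seed drives everything through a counter-based
`child_seed()` scheme, so subject k's data are reproducible regardless of
cohort size or evaluation order.

## Preprocessing chain and numerical choices

The chain is: 0.1 Hz high-pass → 50 Hz notch → 0.5–30 Hz band →
extended-Infomax ICA with EOG-correlated component removal → 1000 ms
epochs (−200 to +798 ms, half-open, 500 samples) → baseline correction
over [−200, 0) ms → automatic rejection → random epoch equalization →
minimum-epoch check.

**Zero-phase filtering.** Filter orders are unstated in the underlying
protocol, so the package defaults to Butterworth order 2 for the 0.1 Hz
high-pass and order 4 per section elsewhere — conventional, stable
choices. The 0.5–30 Hz band is a high-pass/low-pass cascade rather than a
single band-pass polynomial, which is numerically robust when the band
spans nearly two decades at 500 Hz sampling. Zero-phase application is
implemented spectrally: the FFT of the reflection-padded signal is
multiplied by the cascade's squared magnitude response |H(f)|², which is
the frequency-domain statement of forward–backward (filtfilt) filtering
with doubled effective order; it agrees with time-domain filtfilt to
~1e−7 away from the edges and is what makes cohort-scale runs cheap.
Because every stage is diagonal in the frequency domain, the pipeline
composes all stages into one response (`filter_chain()`); equivalence
with sequential application is property-tested. The notch is a
second-order IIR biquad, quality factor 30.

One consequence worth knowing: a 0.5 Hz high-pass attenuates a slow
Gaussian bump. At the default 120 ms FWHM the chain transmits ~94% of
the injected peak (computed analytically from the response;
monotonically worse for wider templates). Latency is unaffected — the
zero-phase property is exact. Amplitude "ground truth recovery" is
therefore checked against the attenuation-corrected value, and users
comparing absolute amplitudes across different band settings should
expect this few-percent scaling.

**ICA.** Extended Infomax (natural-gradient maximum likelihood with
sub/super-Gaussian switching by the sign of the excess kurtosis of each
activation) is fitted in batch mode on an evenly decimated subsample
(pipeline default 8000 points, 200 iterations; the standalone function
defaults higher). The learning rate anneals when the gradient norm grows
and a diverging run restarts at half the rate; non-convergence is a
flagged warning, not an error. The EOG channel is *included* in the
decomposition in the pipeline: with only three scalp channels, a blink
pattern (steep frontal gradient) overlaps a nearly uniform midline P300
topography badly, and removing a 3-channel blink component costs up to a
quarter of the frontal ERP. Anchoring the blink component to the EOG axis
reduces that loss to a few percent while still removing >90% of blink
RMS; this is also common practice when few channels are available.
Components are flagged automatically when their activation correlates
with the EOG trace at |r| ≥ 0.7 — a reproducible proxy for the manual,
EOG-guided selection clinical pipelines describe.

**Rejection.** An epoch is rejected when any tested channel violates any
criterion: |x| > 70 µV; adjacent-sample step > 50 µV/ms (the only
well-defined discrete reading of a µV/ms bound, Δt = 2 ms); peak-to-peak
range > 50 µV in any sliding 200 ms window; range < 0.5 µV in any sliding
100 ms window. Windows slide over every offset (the stricter reading, and
what common analyzers do), implemented with a doubling running-extreme
so whole cohorts stay vectorized. The EOG channel is excluded from
testing — ocular activity legitimately exceeds the thresholds and is
removed upstream. The flatline criterion exists to catch dead channels;
noiseless synthetic data is *exactly* flat pre-stimulus, so ground-truth
recovery tests set `min_activity` to a negligible value instead of
dropping the criterion.

**Equalization and averaging.** The condition with more retained epochs
is randomly subsampled (seeded, without replacement) to the smaller
count; subjects with fewer than 20 retained epochs in either condition
are excluded at pipeline level, as are subjects whose reported target
count misses the true count by more than 10%. Averages are arithmetic
means over retained epochs; grand averages weigh subjects equally.

**Peak measurement.** "Maximum peak" is read as the global maximum in the
closed 300–600 ms window, boundary samples eligible, ties to the earliest
sample — robust and parameter-free; a local-maxima mode (which refuses
window-edge maxima and falls back to the global rule when the window
contains no interior peak) is available behind `local = TRUE`.

## Statistics

* Pooled (Student) rather than Welch t-tests throughout: every published
  df in the target analysis is `n1 + n2 − 2`. Summary-statistic and
  raw-sample forms are algebraically identical and both exposed; degenerate
  zero-variance inputs give `t = 0, p = 1` (equal means) or an error.
* The mixed ANOVA uses the univariate error-strata decomposition
  (`aov` with `Error(subject/(condition*channel))`): group is tested
  against subjects-within-groups (df 1, 38 at 20 + 20), each within
  effect and its group interaction against its effect-by-subject error.
  Greenhouse–Geisser epsilon is computed from the pooled within-group
  covariance of the repeated measures and reported alongside; headline
  p-values stay uncorrected because the published dfs are integer.
  Partial eta squared is a convenience column. Degenerate designs (zero
  error SS, missing cells) error rather than impute.
* Post-hoc family: the four simple effects on electrode-averaged latency
  — paired target-vs-non-target within each group, pooled independent
  HC-vs-MCI within each condition — with Bonferroni multiplier 4. This is
  the only family consistent with an interaction reported at df (1, 38)
  and four p-values.
* Correlations: Pearson r with pairwise deletion; p from the exact t
  transform; zero-variance scores (e.g. every control at the recognition
  ceiling) yield undefined rows that stay in the report but leave the FDR
  family. Benjamini–Hochberg is applied within each population ×
  condition panel (3 channels × 2 measures × 10 tests); the family choice
  is configurable because the underlying protocol states only that an
  FDR criterion was used.

## What the tests do and do not show

The suite verifies round-trip I/O against the BrainVision format,
filter responses against closed-form Butterworth/notch magnitudes and
`signal::filtfilt`, ICA on known mixtures, the rejection truth table,
the ANOVA against a brute-force cell-means partition and a group-label
permutation oracle, type-I calibration of the interaction test
(0.05 ± 0.02 over 2000 null cohorts), and end-to-end recovery: across 12
seeded calibrated cohorts of 20 + 20 subjects (8 in the acceptance
script; sizes chosen to keep the default runs to minutes), pooled
recovered group-mean target latencies land within a few ms of the
calibration cells, the injected ~33 ms group gap is detected
(interaction p < 0.05) in effectively every cohort, and subject-level
mean absolute recovery error stays below 12 ms / 0.8 µV at the default
noise level.

Passing these tests shows the chain is faithful to its own generative
model — not that the generator reproduces real EEG. Known
simplifications: a Gaussian single-component template (no P3a/P3b
structure, no latency jitter across trials within a subject beyond the
cell value); stationary noise (no drifts, electrode pops, movement or
muscle artifacts, so rejection rates are lower than in practice); blinks
as the only ocular artifact (no saccades; horizontal EOG is not
modelled); three scalp channels (real ICA cleanup uses full caps, where
blink/ERP separation is easier); no volume-conduction head model. Line
noise is off by default (the notch is verified on synthetic sinusoids);
marker codes default to `"S  1"`/`"S  2"` as a configurable convention,
since stimulus codes are site-specific; the uniform ISI distribution is
an assumption. These are the points to revisit before treating synthetic
performance as a forecast for any particular laboratory's recordings.
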