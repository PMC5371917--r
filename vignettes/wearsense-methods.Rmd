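---
title: "Methods: higher-order spectral features for stereotypical-movement detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: higher-order spectral features for stereotypical-movement detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Stereotypical motor movements (SMMs) — repetitive, invariant behaviors such
as hand flapping or self-hitting — are common in autism spectrum disorder,
and reliable automatic detection of them from a wrist-worn accelerometer
would let caregivers and clinicians monitor frequency and response to
intervention outside the clinic. `wearsense` implements a complete detection
pipeline for 50 Hz tri-axial wrist accelerometry: recordings are segmented
into 2-second windows, each window is summarized by a fixed battery of 102
features with an emphasis on higher-order spectra, and windows are classified
into three behavior classes — *flapping* (sustained quasi-periodic arm
oscillation), *painting* (a writing/drawing-like daily activity used as a
contrast class), and *sibbing* (self-directed hitting on the top of the
head) — by a bagged ensemble of decision trees.

No public recordings exist for this task at this sampling configuration, so
the package ships a synthetic motion generator as a first-class, tested
module. Everything downstream of ingestion is exercised end-to-end against
generated data.

## Signal model and feature battery

Each window is a 100-sample, 3-axis segment (2 s at 50 Hz). Per axis the
battery computes 34 features in seven families; the full vector is the
concatenation over axes x, y, z, fixed by a versioned registry
(`feature_registry()`, shipped as `extdata/feature_manifest.csv`).

**Time domain (5).** Max, min, peak-to-peak, variance on the raw samples,
plus the Shannon entropy (bits) of a 16-bin histogram of the mean-removed
amplitudes. Mean removal makes the entropy offset-invariant; equal-width
bins over the observed range make it scale-invariant.

**FFT (6).** On the mean-removed window: dominant frequency and magnitude,
spectral centroid, spectral entropy, and band-energy fractions in 0–3 Hz and
3–12 Hz. The bands bracket the drift-dominated painting class below and the
flapping fundamental/harmonic region above.

**DCT (5).** Magnitudes of the first four post-DC DCT-II coefficients and
the energy fraction carried by the first ten — a compact shape descriptor of
slow trends.

**z-transform (4).** `|Σ s[n] z^{-n}|` at radius 0.95 and angles π/8, π/4,
π/2, 3π/4. Evaluating *off* the unit circle is deliberate: on it the
z-transform is the DTFT and the family would duplicate the FFT features; the
0.95 radius damps late samples and gives a genuinely different projection.

**Bispectrum (6).** The direct segment-averaged estimator
`B(f1, f2) = E[X(f1) X(f2) X*(f1 + f2)]` (segments of 50 samples,
mean-removed, zero-padded to nfft = 64). The bispectrum vanishes for
Gaussian processes and concentrates at quadratically phase-coupled
frequency pairs, so its magnitude summaries index the non-Gaussian,
nonlinear character of the motion. Features: max, mean and sum of the
magnitude over the principal domain (`0 ≤ f2 ≤ f1`, `f1 + f2 ≤ fs/2`), two
bispectral entropies (of the normalized magnitudes and of their squares),
and the f1 coordinate of the argmax.

**Wigner bispectrum (5)** and **Wigner trispectrum diagonal (3).** The
time-varying higher-order spectra. The order-k Wigner spectrum Fourier
transforms, over k lags, a (k+1)-fold product of signal values at fractional
lag offsets; for k = 2 the offsets are thirds of a lag, for k = 3 quarters.
Two realization choices matter:

* *Fractional lags by band-limited oversampling.* The third- and
  quarter-sample shifts are evaluated on 3x (bispectrum) or 4x
  (trispectrum) Fourier-interpolated copies of the window, so they are exact
  for band-limited content. Nearest-neighbour rounding would break the
  lag-swap symmetry and the amplitude-scaling laws that the test suite
  asserts.
* *Only the trispectrum diagonal (`τ1 = τ2 = τ3`) is materialized.* The full
  4-D object on a 100-sample window is large and is only ever reduced to
  scalar summaries; the diagonal slice retains the quartic (kurtosis-like)
  phase information and scales as amplitude^4, which the features exploit.

Features: global max/mean/entropy of the magnitude over the non-negative
frequency quadrant, the time-averaged diagonal maximum and the diagonal peak
frequency (Wigner bispectrum); diagonal max/mean/entropy (trispectrum).

The frozen spectral parameters are `max_lag = 24` samples (about half a
window), time decimation 4 for the time-varying spectra, `nfft = 64`,
segment length 50 (`hos_feature_params()`). Windows are mean-removed per
axis before every spectral family so the gravity DC line on z never leaks
into the spectra; raw values feed only the time-domain extrema.

The order-1 Wigner-Ville distribution itself (`wvd()`) uses the analytic
signal (FFT Hilbert transform) to suppress positive/negative frequency
cross-terms — the standard realization for real inputs.

### Degenerate inputs and conventions

Constant or all-zero windows are valid: every entropy of a degenerate
distribution is defined as 0 (with the `0·log 0 = 0` convention), dominant
and peak frequencies of an empty spectrum are 0, and the extractor
guarantees finite output for any finite input (fuzz-tested). All entropies
are in bits.

The per-axis feature list is this package's canonical reconstruction of a
"34 features per axis" battery spanning the named families; the registry is
versioned, shipped as a manifest, and embedded in persisted models so a
model can never silently be applied to features from a different registry.

## Synthetic data generator

The generator emulates the study design the pipeline targets: 20-s
single-task recordings at 50 Hz, three balanced classes, 55 recordings per
class (165 total), spread round-robin over 14 synthetic subjects.

* *Flapping*: amplitude-modulated (0.3 Hz, depth 0.3) oscillation at 3 Hz
  with a phase-locked second harmonic, dominant on x and z. The dominant-axis
  waveform is peak-normalized so the `amplitude` parameter (default 8 m/s²)
  is the true peak acceleration.
* *Painting*: sum of four random low-frequency (< 1.5 Hz) sinusoids (drift of
  the writing hand) plus a 4–6 Hz tremor whose prominence varies per
  recording (10–45% of the drift amplitude); amplitude 1.2 m/s², dominant
  on x/y.
* *Sibbing*: Poisson impact train at 1.5 events/s of exponentially decaying
  spikes (60 ms time constant, amplitude 12 m/s²) on z over a quiet baseline.

All classes add gravity (9.81 m/s²) on z and white Gaussian noise
(`noise_sd`, default 0.3 m/s²). Individual variation enters at two levels:
each synthetic subject carries a fixed ±15% jitter on base frequency and
amplitude, and each recording additionally draws its own tempo/rate and
amplitude factors from class-specific ranges (flapping tempo 0.75–1.5×,
amplitude 0.25–1.4×; painting amplitude 0.4–2.5×; sibbing rate 0.55–1.65×,
amplitude 0.4–1.3×). The ranges deliberately overlap across classes — a
low-amplitude slow flap meets a vigorous tremor-heavy painting recording —
so no single feature threshold separates the classes and classifier
comparisons probe genuinely conjunctive decision boundaries, while the
classes remain recoverable from spectral shape, harmonic phase coupling and
impulsiveness together. Amplitudes, rates and decay constants are invented —
plausible magnitudes for vigorous arm movement, handwriting micro-movement,
and head impacts — because no public reference states them; the overlap
ranges were calibrated once against the requirement that the default
dataset be separable but not trivially so, and then frozen.

Per-recording RNG streams derive from the dataset seed plus a counter, so
generating more recordings never changes earlier ones, and a fixed seed
reproduces the dataset bit-identically.

**What passing tests do and do not show.** The generator produces
class-separable, subject-varying, noisy signals with the right gross
spectral signatures (periodic vs. drift vs. impulsive), so it validates the
plumbing, the spectra, and the learning machinery end-to-end. It does not
capture watch orientation drift, gait and posture artifacts, behavior
transitions inside a window, or the heavy-tailed inter-subject variability
of real wrist data — classifier accuracies on it say nothing quantitative
about accuracy on real recordings.

## Classification and evaluation

The classifier is bootstrap aggregation of 40 unpruned CART trees (Gini
splits, grown to purity) with majority vote; ties break toward the first
class in the fixed order (flapping, painting, sibbing). Evaluation is
stratified 10-fold cross-validation repeated 10 times: folds are re-drawn
per repeat, every sample is tested exactly once per repeat, and the
confusion matrix is pooled, which makes the mean-over-repeats accuracy
identical to `trace/sum` of the pooled matrix. Stratification assigns each
class's remainder samples to the least-loaded folds, so global fold sizes
differ by at most one (165 samples, K = 10 gives sizes 16–17); `K = n` is
treated as leave-one-out, where stratification is vacuous. Multiclass ROC is
realized as one-vs-rest curves from the vote fractions with the macro AUC by
the Mann-Whitney rank statistic (midranks for ties).

The comparison harness runs six models on one shared fold assignment:
complex tree (≤ 100 splits), simple tree (≤ 4 splits), linear and
Gaussian-kernel SVMs (`e1071`), SAMME adaptive boosting of 30 shallow trees,
and the 40-tree bagged ensemble. Split budgets are configuration, not
hard-coded. Training time is reported for orientation only; it is
hardware-dependent and excluded from automated checks.

## Numerical choices

* Timestamp jitter tolerance on ingestion: |Δt − 1/fs| ≤ 0.2/fs per step;
  within tolerance the grid is regularized, beyond it the file is rejected
  with the offending row named. Windows default to non-overlapping
  (overlap is a parameter).
* CSV values are written with 10 significant digits, so write/read
  round-trips are exact well beyond sensor resolution.
* The bispectrum estimator uses rectangular (untapered) segments; this keeps
  the estimator identical to its direct-summation definition. With
  `nfft = 64` at 50 Hz the 6 and 9 Hz test tones fall between bins and
  leakage makes the peak's nearest-bin location ambiguous by one bin, so the
  exact phase-coupling localization test uses `nfft = 50`, where integer
  frequencies are on-grid.
* Oracle tests: every FFT-accelerated spectrum is checked against a literal
  direct-summation implementation (independent trigonometric interpolation,
  explicit DFT sums) to relative error below 1e-9 on random signals.
* Problem sizes in the test suite are desk-scale by design: oracle
  comparisons run at N ≤ 64 with max_lag ≤ 8, and the end-to-end recovery
  check uses the full default dataset (165 recordings, 1650 windows).

## Known limitations

* The motion models are phenomenological; see above for what that implies.
* The Wigner trispectrum is computed only on its lag diagonal; off-diagonal
  structure is not exposed.
* No cross-axis features (e.g. magnitude-vector features) and no feature
  selection — the battery is fixed by the registry.
* Subject identity is not used for fold grouping; cross-validation estimates
  within-population window-level accuracy, not leave-subject-out
  generalization.
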