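# wearsense

Detection of stereotypical motor movements (SMMs) — hand **flapping**,
**painting** (a writing/drawing contrast activity), and **sibbing**
(self-directed hitting on the top of the head) — from 50 Hz tri-axial
wrist-worn accelerometer recordings. The package is aimed at researchers in
wearable digital health and human activity recognition who need a
reproducible, fully testable reference pipeline for higher-order-spectrum
feature engineering and tree-ensemble classification of short accelerometer
windows.

## Method

Recordings (`timestamp,x,y,z` CSV) are segmented into 2-s windows
(100 samples). Each window is summarized by a frozen battery of **102
features** — 34 per axis — spanning:

* time-domain statistics (extrema, variance, amplitude-histogram entropy);
* FFT summaries (dominant frequency/magnitude, spectral centroid and
  entropy, 0–3 Hz and 3–12 Hz band-energy fractions);
* DCT-II coefficients and z-transform magnitudes at radius 0.95;
* the **bispectrum** — the direct segment-averaged estimator
  `B(f₁,f₂) = E[X(f₁)X(f₂)X*(f₁+f₂)]`, which vanishes for Gaussian signals
  and peaks at quadratically phase-coupled frequency pairs;
* the time-varying **Wigner bispectrum** and the diagonal slice of the
  **Wigner trispectrum**, the order-2 and order-3 Wigner higher-order
  spectra, with fractional lag shifts handled exactly by band-limited
  oversampling (×3 and ×4).

Windows are classified by **bagging**: an ensemble of 40 unpruned CART
decision trees (Gini splits), each trained on a bootstrap resample, combined
by majority vote. Evaluation is stratified 10-fold cross-validation averaged
over 10 repeats, with a pooled confusion matrix and one-vs-rest macro ROC
AUC, plus a six-classifier comparison harness (complex/simple tree,
linear/Gaussian SVM, boosted trees, bagged trees) on shared folds.

Because no public recordings exist for this configuration, the package ships
a tested synthetic motion generator for the three classes (periodic
oscillation / low-frequency drift plus tremor / Poisson impact train, with
per-subject variation and sensor noise) so the entire pipeline runs and is
validated end-to-end out of the box. See `vignettes/wearsense-methods.Rmd`
for the full model description and design rationale.

## Worked example

```r
library(wearsense)

cfg <- run_config(n_per_class = 8, duration = 10, K = 5, n_repeats = 2,
                  n_trees = 20, seed = 42, output_dir = tempfile())
res <- run_pipeline(cfg)
print(res$cv)
```

```
synth: generating 8 recordings/class x 10 s at 50 Hz (seed 42)
window: 24 recordings -> 120 windows of 100 samples (overlap 0)
features: 120 x 102 matrix
cv: overall accuracy 99.2%, macro AUC 1.000
<cv_report> 5-fold CV x 2 repeats on 120 samples
  overall accuracy: 99.2%  macro AUC: 1.000
          predicted
true       flapping painting sibbing
  flapping       78        2       0
  painting        0       80       0
  sibbing         0        0      80
```

The log lines trace the pipeline stages: 24 synthetic recordings become 120
two-second windows, each reduced to the 102-feature vector; the bagged
ensemble then classifies 99.2% of windows correctly across the two CV
repeats (each window is tested once per repeat, so the confusion matrix sums
to 240), and the macro one-vs-rest AUC is 1.000. The residual confusions are
low-amplitude slow flapping windows that resemble tremor-heavy painting —
the deliberate overlap region of the generative models.

A command-line front end is installed with the package
(`<library>/wearsense/exec/wearsense`) with subcommands `synth`, `extract`,
`run`, and `compare`, reading a flat YAML config overridden by flags.

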