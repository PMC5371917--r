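Package: wearsense
Title: Higher-Order Spectral Features and Bagged-Tree Classification of
    Wrist-Worn Accelerometer Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects stereotypical motor movements (hand flapping, painting,
    self-hitting) from 50 Hz tri-axial wrist accelerometer recordings. Provides
    CSV ingestion and 2-second windowing, a synthetic motion generator for the
    three behavior classes, higher-order spectral machinery (direct bispectrum
    estimator, discrete pseudo Wigner-Ville distribution, Wigner bispectrum and
    diagonal Wigner trispectrum with band-limited fractional-lag handling), a
    frozen 102-feature battery (34 features per axis spanning time-domain, FFT,
    DCT, z-transform and higher-order-spectrum families), and a bagged ensemble
    of 40 unpruned CART decision trees evaluated by repeated stratified 10-fold
    cross-validation with one-vs-rest ROC/AUC and a six-classifier comparison
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    rpart,
    e1071,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
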