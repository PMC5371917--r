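# Higher-order spectra: trivial cases, physics of the Wigner-Ville
# distribution, oracle equivalence, symmetry and scaling laws.

test_that("zero input yields zero spectra everywhere", {
  z <- numeric(64)
  expect_true(all(bispectrum(z, nfft = 32, segment_len = 16)$values == 0))
  expect_true(all(wvd(z, 50)$values == 0))
  expect_true(all(wigner_bispectrum(z, 50, max_lag = 8)$values == 0))
  expect_true(all(wigner_trispectrum_diag(z, 50, max_lag = 8)$values == 0))
})

test_that("bispectrum of coupled tones peaks at the coupled pair", {
  fs <- 50
  t <- (0:499) / fs
  x <- cos(2 * pi * 6 * t) + cos(2 * pi * 9 * t) + cos(2 * pi * 15 * t)
  # off-grid bins (nfft 64): peak within one bin of (6, 9)
  bs <- bispectrum(x, nfft = 64, segment_len = 50, fs = fs)
  v <- bs$values
  v[!bispectrum_principal_mask(bs)] <- -Inf
  ij <- arrayInd(which.max(v), dim(v))
  got <- sort(bs$f_axis[ij])
  expect_lte(abs(got[1] - 6), fs / 64)
  expect_lte(abs(got[2] - 9), fs / 64)
  # aligned grid (nfft 50): peak exactly at {6, 9} Hz
  bs2 <- bispectrum(x, nfft = 50, segment_len = 50, fs = fs)
  v2 <- bs2$values
  v2[!bispectrum_principal_mask(bs2)] <- -Inf
  ij2 <- arrayInd(which.max(v2), dim(v2))
  expect_equal(sort(bs2$f_axis[ij2]), c(6, 9))
})

test_that("bispectrum matches a one-segment hand computation at nfft 64", {
  set.seed(7)
  x <- rnorm(64)
  got <- bispectrum(x, nfft = 64, segment_len = 64)$values
  want <- oracle_bispectrum(x, nfft = 64, segment_len = 64)
  expect_lt(max_rel_err(got, want), 1e-10)
})

test_that("bispectrum grids are symmetric under frequency swap", {
  for (seed in 1:5) {
    set.seed(seed)
    v <- bispectrum(rnorm(120), nfft = 32, segment_len = 30)$values
    expect_lt(max(abs(v - t(v))), 1e-10 * max(v))
  }
})

test_that("WVD concentrates a pure tone at its frequency", {
  fs <- 50
  x <- sin(2 * pi * 5 * (0:499) / fs)
  W <- wvd(x, fs)
  nearest <- which.min(abs(W$f_axis - 5))
  for (fr in seq(50, 450, by = 25))
    expect_equal(which.max(W$values[fr, ]), nearest)
})

test_that("WVD time marginal equals instantaneous power times bin count", {
  fs <- 50
  x <- sin(2 * pi * 5 * (0:499) / fs) + 0.3 * sin(2 * pi * 11 * (0:499) / fs)
  W <- wvd(x, fs)
  z <- analytic_signal(x)
  M <- 2 * W$max_lag + 1
  for (fr in seq(60, 440, by = 40)) {
    want <- M * Mod(z[fr])^2
    expect_lt(abs(sum(W$values[fr, ]) - want) / want, 1e-6)
  }
})

test_that("shifting the signal shifts the WVD energy ridge in time", {
  fs <- 50
  n <- 300
  burst <- function(center) {
    t <- (0:(n - 1)) / fs
    exp(-((t - center / fs) / 0.2)^2) * sin(2 * pi * 6 * t)
  }
  marg <- function(x) rowSums(wvd(x, fs)$values)
  s <- 40
  expect_equal(which.max(marg(burst(100 + s))), which.max(marg(burst(100))) + s)
})

test_that("Wigner bispectrum equals its brute-force oracle", {
  set.seed(13)
  x <- rnorm(48)
  got <- wigner_bispectrum(x, 50, max_lag = 8, time_decim = 4)$values
  want <- oracle_wigner_bispectrum(x, max_lag = 8, time_decim = 4)
  expect_lt(max_rel_err(got, want), 1e-9)
})

test_that("Wigner bispectrum is symmetric under lag/frequency swap", {
  for (seed in 1:5) {
    set.seed(seed)
    v <- wigner_bispectrum(rnorm(60), 50, max_lag = 8)$values
    expect_lt(max(abs(v - aperm(v, c(1, 3, 2)))), 1e-10 * max(v))
  }
})

test_that("diagonal Wigner trispectrum equals its brute-force oracle", {
  set.seed(21)
  x <- rnorm(48)
  got <- wigner_trispectrum_diag(x, 50, max_lag = 6, time_decim = 4)$values
  want <- oracle_wigner_trispectrum_diag(x, max_lag = 6, time_decim = 4)
  expect_lt(max_rel_err(got, want), 1e-9)
})

test_that("a constant signal concentrates trispectral energy at DC", {
  wt <- wigner_trispectrum_diag(rep(2.5, 64), 50, max_lag = 8)
  expect_gte(sum(wt$values[, 1]) / sum(wt$values), 0.99)
})

test_that("spectra obey their amplitude scaling laws", {
  set.seed(3)
  x <- rnorm(100)
  a <- 1.7
  b1 <- bispectrum(x, nfft = 32, segment_len = 25)$values
  b2 <- bispectrum(a * x, nfft = 32, segment_len = 25)$values
  expect_equal(b2, a^3 * b1, tolerance = 1e-10)
  w1 <- wigner_bispectrum(x, 50, max_lag = 8)$values
  w2 <- wigner_bispectrum(a * x, 50, max_lag = 8)$values
  expect_equal(w2, a^3 * w1, tolerance = 1e-10)
  t1 <- wigner_trispectrum_diag(x, 50, max_lag = 8)$values
  t2 <- wigner_trispectrum_diag(a * x, 50, max_lag = 8)$values
  expect_equal(t2, a^4 * t1, tolerance = 1e-10)
})

test_that("Gaussian noise is bispectrally suppressed relative to coupled tones", {
  fs <- 50
  t <- (0:499) / fs
  coupled <- cos(2 * pi * 6 * t) + cos(2 * pi * 9 * t) + cos(2 * pi * 15 * t)
  mean_bis <- function(x) {
    bs <- bispectrum(x, nfft = 64, segment_len = 50, fs = fs)
    mean(bs$values[bispectrum_principal_mask(bs)])
  }
  ref <- mean_bis(coupled)
  set.seed(5)
  noise_means <- replicate(20, mean_bis(rnorm(500, sd = sqrt(1.5))))
  expect_lt(mean(noise_means), ref)
})

test_that("spectrum grids dump to readable plain-text matrices", {
  bs <- bispectrum(sin(2 * pi * 5 * (0:99) / 50), nfft = 32, segment_len = 25)
  p <- withr::local_tempfile()
  write_spectrum_grid(bs, p)
  got <- as.matrix(read.table(p))
  expect_equal(unname(got), unname(bs$values), tolerance = 1e-6)

  wb <- wigner_bispectrum(rnorm(48), 50, max_lag = 6)
  p2 <- withr::local_tempfile()
  write_spectrum_grid(wb, p2)
  expect_equal(sum(grepl("^# frame", readLines(p2))), dim(wb$values)[1])
})

test_that("length preconditions raise informative input errors", {
  expect_error(bispectrum(rnorm(10), nfft = 32, segment_len = 32),
               class = "ws_input_error")
  expect_error(wigner_bispectrum(rnorm(20), 50, max_lag = 8),
               class = "ws_input_error")
  expect_error(wigner_bispectrum(rnorm(20), 50, max_lag = 8), "24")
  expect_error(wigner_trispectrum_diag(rnorm(20), 50, max_lag = 8),
               class = "ws_input_error")
})
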