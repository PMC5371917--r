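# Higher-order spectral machinery: direct bispectrum estimator, discrete
# pseudo Wigner-Ville distribution, and the time-varying Wigner bispectrum /
# diagonal Wigner trispectrum.
#
# The Wigner higher-order spectra involve fractional lag shifts (thirds for
# the bispectrum, quarters for the trispectrum). These are realized exactly
# for band-limited signals by Fourier zero-padding interpolation (x3 and x4
# oversampling respectively), not by nearest-neighbour rounding, so the
# symmetry and scaling properties of the definitions survive discretization.

#' Analytic signal via the FFT Hilbert transform
#'
#' Removes negative-frequency content from a real series, the standard
#' realization used before the Wigner-Ville distribution to suppress
#' cross-terms between positive and negative frequencies.
#'
#' @param x Real numeric series.
#' @return Complex series of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2) return(complex(real = as.numeric(x), imaginary = numeric(n)))
  X <- stats::fft(as.numeric(x))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Band-limited (trigonometric) interpolation onto a grid `factor` times finer.
# For even lengths the Nyquist coefficient is split between +/- Nyquist so the
# result is real and agrees with direct evaluation of the symmetric
# trigonometric interpolant.
oversample_bandlimited <- function(x, factor) {
  x <- as.numeric(x)
  n <- length(x)
  m <- n * factor
  X <- stats::fft(x)
  Y <- complex(length.out = m)
  if (n %% 2 == 0) {
    half <- n / 2
    Y[seq_len(half)] <- X[seq_len(half)]
    Y[half + 1] <- X[half + 1] / 2
    Y[m - half + 1] <- X[half + 1] / 2
    if (half >= 2) Y[(m - half + 2):m] <- X[(half + 2):n]
  } else {
    half <- (n - 1) / 2
    Y[seq_len(half + 1)] <- X[seq_len(half + 1)]
    if (half >= 1) Y[(m - half + 1):m] <- X[(half + 2):n]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

new_spectrum_grid <- function(values, f_axis, t_axis = NULL, order,
                              max_lag = NA_integer_) {
  structure(
    list(values = values, f_axis = f_axis, t_axis = t_axis, order = order,
         max_lag = max_lag),
    class = "spectrum_grid"
  )
}

#' @export
print.spectrum_grid <- function(x, ...) {
  cat(sprintf("<spectrum_grid> order %d, dims [%s], %d frequency bins%s\n",
              x$order, paste(dim(as.array(x$values)), collapse = " x "),
              length(x$f_axis),
              if (is.null(x$t_axis)) "" else sprintf(", %d time frames",
                                                     length(x$t_axis))))
  invisible(x)
}

#' Direct (Fourier-domain) bispectrum estimator
#'
#' Third-order spectrum of a stationary series: the signal is cut into
#' non-overlapping segments, each mean-removed and zero-padded to `nfft`, and
#' `B(f1, f2) = X(f1) X(f2) X*(f1 + f2)` is averaged over segments. The
#' bispectrum vanishes for Gaussian signals and peaks at quadratically
#' phase-coupled frequency pairs, which is what makes it informative about
#' nonlinear motion. The returned magnitude grid covers
#' `f1, f2 in [0, fs/2]` and is symmetric under swapping `f1` and `f2`; the
#' non-redundant principal domain is `0 <= f2 <= f1, f1 + f2 <= fs/2` (see
#' [bispectrum_principal_mask()]).
#'
#' @param x Real numeric series, at least one segment long.
#' @param nfft FFT length (default 64, must be >= `segment_len`).
#' @param segment_len Segment length in samples (default `min(length(x),
#'   nfft)`, at least 8).
#' @param fs Sampling rate in Hz for the frequency axis.
#' @return A `spectrum_grid` with a `(nfft/2 + 1)` square magnitude matrix.
#' @export
bispectrum <- function(x, nfft = 64, segment_len = NULL, fs = 50) {
  x <- as.numeric(x)
  n <- length(x)
  segment_len <- segment_len %||% min(n, nfft)
  if (segment_len < 8) abort_input("segment_len must be at least 8 samples")
  if (n < segment_len)
    abort_input(sprintf("series of length %d is shorter than one segment (%d)",
                        n, segment_len))
  if (nfft < segment_len) abort_input("nfft must be >= segment_len")
  nseg <- n %/% segment_len
  K <- nfft %/% 2
  k1 <- 0:K
  sum_idx <- (outer(k1, k1, "+") %% nfft) + 1L
  acc <- matrix(0 + 0i, K + 1L, K + 1L)
  for (s in seq_len(nseg)) {
    seg <- x[((s - 1L) * segment_len + 1L):(s * segment_len)]
    seg <- seg - mean(seg)
    X <- stats::fft(c(seg, numeric(nfft - segment_len)))
    acc <- acc + outer(X[k1 + 1L], X[k1 + 1L]) *
      Conj(matrix(X[sum_idx], K + 1L, K + 1L))
  }
  new_spectrum_grid(Mod(acc / nseg), f_axis = k1 * fs / nfft, order = 2,
                    max_lag = NA_integer_)
}

#' Principal-domain mask of a bispectrum grid
#'
#' Logical matrix marking the non-redundant triangle `0 <= k2 <= k1`,
#' `k1 + k2 <= nfft/2` of a [bispectrum()] grid; the full grid follows from
#' this region by symmetry.
#'
#' @param grid A `spectrum_grid` from [bispectrum()].
#' @return Logical matrix with the grid's dimensions.
#' @export
bispectrum_principal_mask <- function(grid) {
  K <- nrow(grid$values) - 1L
  k1 <- 0:K
  outer(k1, k1, function(a, b) b <= a & a + b <= K)
}

#' Discrete pseudo Wigner-Ville distribution
#'
#' Bilinear time-frequency representation: for each time index `n`, the lag
#' product `z(n + m) z*(n - m)` of the analytic signal is Fourier-transformed
#' over lags `|m| <= max_lag` (clipped at the series edges). The real part is
#' returned; a pure tone concentrates along its frequency, and summing a
#' frame over all frequency bins returns `(2 max_lag + 1) |z(n)|^2`
#' (instantaneous power times the bin count).
#'
#' @param x Real numeric series of length >= 8.
#' @param fs Sampling rate, Hz.
#' @param max_lag Half-width of the lag window in samples (default 24).
#' @return A `spectrum_grid` with an `n x (2 max_lag + 1)` real matrix,
#'   `t_axis` in seconds and `f_axis = k fs / (2(2 max_lag + 1))` spanning
#'   `[0, fs/2)`. Values are signed (order-1 distribution, not a magnitude).
#' @export
wvd <- function(x, fs = 50, max_lag = 24) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8) abort_input("series too short for a Wigner-Ville distribution")
  z <- analytic_signal(x)
  L <- min(max_lag, (n - 1) %/% 2)
  M <- 2L * L + 1L
  W <- matrix(0, n, M)
  for (ni in 0:(n - 1L)) {
    Ln <- min(L, ni, n - 1L - ni)
    m <- (-Ln):Ln
    kern <- complex(length.out = M)
    kern[(m %% M) + 1L] <- z[ni + m + 1L] * Conj(z[ni - m + 1L])
    W[ni + 1L, ] <- Re(stats::fft(kern))
  }
  new_spectrum_grid(W, f_axis = (0:(M - 1L)) * fs / (2 * M),
                    t_axis = (0:(n - 1L)) / fs, order = 1, max_lag = L)
}

#' Time-varying Wigner bispectrum
#'
#' Order-2 Wigner higher-order spectrum of a real series: at each retained
#' time frame `t` the 2-D Fourier transform over integer lags
#' `tau1, tau2 in [-max_lag, max_lag]` of the triple product
#' `x*(t - tau1/3 - tau2/3) x(t + 2 tau1/3 - tau2/3) x(t + 2 tau2/3 - tau1/3)`
#' is taken. The third-sample shifts are evaluated on a x3 band-limited
#' oversampled copy of the signal, so they are exact for band-limited content.
#' The magnitude is returned; it is symmetric under swapping the two
#' frequency arguments.
#'
#' @param x Real numeric series of length >= `3 * max_lag`.
#' @param fs Sampling rate, Hz.
#' @param max_lag Maximum lag in (original) samples; default 24.
#' @param time_decim Evaluate every `time_decim`-th admissible frame
#'   (default 4) to bound cost; use 1 for full time resolution.
#' @return A `spectrum_grid` whose `values` is a
#'   `n_frames x (2 max_lag + 1) x (2 max_lag + 1)` magnitude array;
#'   `f_axis = k fs / (2 max_lag + 1)` (bins above `max_lag` alias the
#'   negative frequencies of the real input).
#' @export
wigner_bispectrum <- function(x, fs = 50, max_lag = 24, time_decim = 4) {
  x <- as.numeric(x)
  n <- length(x)
  L <- as.integer(max_lag)
  if (L < 1) abort_config("max_lag must be at least 1")
  if (n < 3 * L)
    abort_input(sprintf(
      "series of length %d too short for max_lag %d; at least %d samples needed",
      n, L, 3 * L))
  x3 <- oversample_bandlimited(x, 3L)
  M <- 2L * L + 1L
  pv <- c(0:L, (-L):(-1L))                  # DFT-wrapped lag ordering
  pp <- rep(pv, times = M)
  qq <- rep(pv, each = M)
  i1 <- -pp - qq
  i2 <- 2L * pp - qq
  i3 <- 2L * qq - pp
  frames <- seq.int(L, n - 1L - L, by = time_decim)
  vals <- array(0, c(length(frames), M, M))
  for (fi in seq_along(frames)) {
    c0 <- 3L * frames[fi] + 1L              # 1-based centre in x3
    A <- x3[c0 + i1] * x3[c0 + i2] * x3[c0 + i3]
    vals[fi, , ] <- Mod(stats::fft(matrix(A, M, M)))
  }
  new_spectrum_grid(vals, f_axis = (0:(M - 1L)) * fs / M,
                    t_axis = frames / fs, order = 2, max_lag = L)
}

#' Diagonal slice of the time-varying Wigner trispectrum
#'
#' Order-3 Wigner higher-order spectrum restricted to equal lags
#' `tau1 = tau2 = tau3 = tau`, where the quadruple product collapses to
#' `x*(t - 3 tau/4) x(t + tau/4)^3` and a single 1-D Fourier transform over
#' `tau` remains. Quarter-sample shifts use a x4 band-limited oversampled
#' copy. The full 4-D trispectrum is never materialized; the diagonal slice
#' carries the quartic phase information used by the feature battery, and its
#' magnitude scales with the 4th power of the signal amplitude.
#'
#' @param x Real numeric series of length >= `4 * max_lag`.
#' @param fs Sampling rate, Hz.
#' @param max_lag Maximum lag in samples; default 24.
#' @param time_decim Frame decimation factor (default 4).
#' @return A `spectrum_grid` with an `n_frames x (2 max_lag + 1)` magnitude
#'   matrix and `f_axis = k fs / (2 max_lag + 1)`.
#' @export
wigner_trispectrum_diag <- function(x, fs = 50, max_lag = 24, time_decim = 4) {
  x <- as.numeric(x)
  n <- length(x)
  L <- as.integer(max_lag)
  if (L < 1) abort_config("max_lag must be at least 1")
  if (n < 4 * L)
    abort_input(sprintf(
      "series of length %d too short for max_lag %d; at least %d samples needed",
      n, L, 4 * L))
  x4 <- oversample_bandlimited(x, 4L)
  M <- 2L * L + 1L
  pv <- c(0:L, (-L):(-1L))
  margin <- ceiling(3 * L / 4)
  frames <- seq.int(margin, n - 1L - margin, by = time_decim)
  vals <- matrix(0, length(frames), M)
  for (fi in seq_along(frames)) {
    c0 <- 4L * frames[fi] + 1L
    A <- x4[c0 - 3L * pv] * x4[c0 + pv]^3
    vals[fi, ] <- Mod(stats::fft(A))
  }
  new_spectrum_grid(vals, f_axis = (0:(M - 1L)) * fs / M,
                    t_axis = frames / fs, order = 3, max_lag = L)
}

#' Dump a spectrum grid to a plain-text matrix file (debug aid)
#'
#' 3-D grids are written frame by frame with a comment line per frame.
#'
#' @param grid A `spectrum_grid`.
#' @param path Output path.
#' @export
write_spectrum_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- grid$values
  if (length(dim(v)) == 3) {
    for (fi in seq_len(dim(v)[1])) {
      writeLines(sprintf("# frame %d t=%.6g", fi, grid$t_axis[fi]), con)
      utils::write.table(v[fi, , ], con, row.names = FALSE, col.names = FALSE)
    }
  } else {
    utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
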