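# Independent brute-force oracles, kept free of the package's FFT-based
# computation paths: DFTs are literal sums (or explicit exponential-matrix
# products), interpolation is direct evaluation of the trigonometric
# interpolant.

# Direct-sum DFT of a (possibly complex) vector.
naive_dft <- function(x) {
  n <- length(x)
  j <- 0:(n - 1)
  vapply(j, function(k) sum(x * exp(-2i * pi * k * j / n)), complex(1))
}

# Band-limited interpolation onto a grid `factor` times finer: evaluate the
# symmetric trigonometric interpolant directly (Nyquist split for even n).
oracle_interp <- function(x, factor) {
  n <- length(x)
  j <- 0:(n - 1)
  ks <- if (n %% 2 == 0) (-(n / 2)):(n / 2) else (-((n - 1) / 2)):((n - 1) / 2)
  ck <- vapply(ks, function(k) sum(x * exp(-2i * pi * k * j / n)), complex(1))
  wk <- ifelse(n %% 2 == 0 & abs(ks) == n / 2, 0.5, 1)
  tt <- (0:(n * factor - 1)) / factor
  vapply(tt, function(t0) Re(sum(wk * ck * exp(2i * pi * ks * t0 / n))) / n,
         numeric(1))
}

# Explicit DFT matrix (literal definition, no FFT).
dft_matrix <- function(M) {
  k <- 0:(M - 1)
  exp(-2i * pi * outer(k, k) / M)
}

# Segment-averaged direct bispectrum by literal sums.
oracle_bispectrum <- function(x, nfft, segment_len) {
  nseg <- length(x) %/% segment_len
  K <- nfft %/% 2
  acc <- matrix(0 + 0i, K + 1, K + 1)
  for (s in seq_len(nseg)) {
    seg <- x[((s - 1) * segment_len + 1):(s * segment_len)]
    seg <- seg - mean(seg)
    X <- naive_dft(c(seg, numeric(nfft - segment_len)))
    for (k1 in 0:K) for (k2 in 0:K)
      acc[k1 + 1, k2 + 1] <- acc[k1 + 1, k2 + 1] +
        X[k1 + 1] * X[k2 + 1] * Conj(X[((k1 + k2) %% nfft) + 1])
  }
  Mod(acc / nseg)
}

# Wigner bispectrum by direct summation over both lags at every frame.
oracle_wigner_bispectrum <- function(x, max_lag, time_decim) {
  n <- length(x)
  L <- max_lag
  M <- 2 * L + 1
  x3 <- oracle_interp(x, 3)
  E <- dft_matrix(M)
  frames <- seq(L, n - 1 - L, by = time_decim)
  vals <- array(0, c(length(frames), M, M))
  lags <- (-L):L
  for (fi in seq_along(frames)) {
    c0 <- 3 * frames[fi]
    A <- matrix(0 + 0i, M, M)   # A[p mod M, q mod M]
    for (p in lags) for (q in lags) {
      A[(p %% M) + 1, (q %% M) + 1] <-
        Conj(x3[c0 - p - q + 1]) * x3[c0 + 2 * p - q + 1] * x3[c0 + 2 * q - p + 1]
    }
    vals[fi, , ] <- Mod(E %*% A %*% t(E))
  }
  vals
}

# Diagonal Wigner trispectrum by direct summation over the single lag.
oracle_wigner_trispectrum_diag <- function(x, max_lag, time_decim) {
  n <- length(x)
  L <- max_lag
  M <- 2 * L + 1
  x4 <- oracle_interp(x, 4)
  E <- dft_matrix(M)
  margin <- ceiling(3 * L / 4)
  frames <- seq(margin, n - 1 - margin, by = time_decim)
  vals <- matrix(0, length(frames), M)
  for (fi in seq_along(frames)) {
    c0 <- 4 * frames[fi]
    A <- complex(length.out = M)
    for (p in (-L):L)
      A[(p %% M) + 1] <- Conj(x4[c0 - 3 * p + 1]) * x4[c0 + p + 1]^3
    vals[fi, ] <- Mod(E %*% A)
  }
  vals
}

# Exhaustive positive-vs-negative pairwise AUC (ties count 1/2).
oracle_auc_pairwise <- function(truth, score, pos_class) {
  pos <- which(truth == pos_class)
  neg <- which(truth != pos_class)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
  tot / (length(pos) * length(neg))
}

# Window count by brute-force enumeration of admissible start indices.
oracle_window_count <- function(N, w, step) {
  count <- 0L
  for (s in seq_len(N)) {
    if (s + w - 1 <= N && (s - 1) %% step == 0) count <- count + 1L
  }
  count
}

max_rel_err <- function(got, want) {
  scale <- max(abs(want))
  if (scale == 0) return(max(abs(got)))
  max(abs(got - want)) / scale
}

random_window <- function(n = 100, fs = 50, seed = 1, label = NULL) {
  set.seed(seed)
  wearsense:::new_window(matrix(stats::rnorm(3 * n), n, 3), fs = fs,
                         label = label)
}
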