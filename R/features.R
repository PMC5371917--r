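# The frozen 34-features-per-axis battery (102 features over x, y, z).
#
# Conventions applied throughout: all entropies are Shannon entropies in bits
# with 0*log(0) = 0 and degenerate (all-zero / single-bin) distributions
# mapped to 0; each axis is mean-removed before every spectral family (this
# drops the gravity DC line on z and makes all non-extremum features
# invariant to constant offsets) while the raw values feed the time-domain
# extrema.

#' Canonical feature registry
#'
#' The ordered, versioned table of the 102 features: 34 per axis in axis
#' blocks x, y, z. Groups per axis: `time` (5), `fft` (6), `dct` (5), `zt`
#' (4), `bispec` (6), `wb` (5), `wt` (3). Names have the form
#' `<axis>_<group>_<feature>`. Models persisted with [save_model()] embed the
#' registry version and refuse to load against a different one.
#'
#' @return A data frame with columns ordinal, name, axis, group, feature,
#'   units (102 rows).
#' @export
feature_registry <- function() {
  if (!is.null(.ws_env$registry)) return(.ws_env$registry)
  g <- function(group, feature, units)
    data.frame(group = group, feature = feature, units = units,
               stringsAsFactors = FALSE)
  per_axis <- rbind(
    g("time", c("max", "min", "peak_to_peak", "variance", "hist_entropy"),
      c("m/s2", "m/s2", "m/s2", "(m/s2)^2", "bits")),
    g("fft", c("dom_freq", "dom_mag", "centroid", "spectral_entropy",
               "band_0_3", "band_3_12"),
      c("Hz", "m/s2", "Hz", "bits", "fraction", "fraction")),
    g("dct", c("c1", "c2", "c3", "c4", "energy_frac_10"),
      c(rep("m/s2", 4), "fraction")),
    g("zt", c("r095_a22", "r095_a45", "r095_a90", "r095_a135"),
      rep("magnitude", 4)),
    g("bispec", c("max", "mean", "sum", "entropy_p1", "entropy_p2", "peak_f1"),
      c(rep("(m/s2)^3", 3), "bits", "bits", "Hz")),
    g("wb", c("max", "mean", "entropy", "diag_max", "diag_peak_freq"),
      c("(m/s2)^3", "(m/s2)^3", "bits", "(m/s2)^3", "Hz")),
    g("wt", c("diag_max", "diag_mean", "diag_entropy"),
      c("(m/s2)^4", "(m/s2)^4", "bits"))
  )
  out <- do.call(rbind, lapply(c("x", "y", "z"), function(a)
    cbind(axis = a, per_axis, stringsAsFactors = FALSE)))
  out$name <- paste(out$axis, out$group, out$feature, sep = "_")
  out$ordinal <- seq_len(nrow(out))
  rownames(out) <- NULL
  .ws_env$registry <- out[, c("ordinal", "name", "axis", "group", "feature", "units")]
  .ws_env$registry
}

#' Registry version embedded in persisted models and the shipped manifest
#' @export
feature_registry_version <- function() "1.0"

#' Frozen higher-order-spectrum parameters used by the feature battery
#'
#' @return List with `max_lag` (24 samples), `nfft` (64), `segment_len` (50)
#'   and `time_decim` (4).
#' @export
hos_feature_params <- function() {
  list(max_lag = 24L, nfft = 64L, segment_len = 50L, time_decim = 4L)
}

#' Export the feature manifest as CSV
#' @param path Output path.
#' @export
write_feature_manifest <- function(path) {
  reg <- feature_registry()
  reg$registry_version <- feature_registry_version()
  utils::write.csv(reg, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# 16-bin amplitude-histogram entropy of the mean-removed series, bits.
hist_entropy_bits <- function(s, bins = 16L) {
  s <- s - mean(s)
  r <- range(s)
  if (diff(r) == 0) return(0)
  width <- diff(r) / bins
  idx <- pmin(bins, pmax(1L, ceiling((s - r[1]) / width)))
  shannon_bits(tabulate(idx, bins))
}

# Unnormalized DCT-II; the cosine matrix is cached per series length.
dct_ii <- function(s) {
  n <- length(s)
  key <- sprintf("dct_%d", n)
  C <- .ws_env[[key]]
  if (is.null(C)) {
    k <- 0:(n - 1)
    C <- cos(pi * outer(k, 2 * k + 1) / (2 * n))
    .ws_env[[key]] <- C
  }
  as.numeric(C %*% s)
}

#' Extract the 34-feature battery from one axis of a window
#'
#' Computes, in registry order: raw-amplitude extrema and variance plus a
#' 16-bin histogram entropy; FFT dominant frequency/magnitude, spectral
#' centroid and entropy, and 0-3 / 3-12 Hz band-energy fractions; the first
#' four post-DC DCT-II coefficient magnitudes and the energy fraction of the
#' first 10; z-transform magnitudes at radius 0.95 and angles pi/8, pi/4,
#' pi/2, 3pi/4 (off the unit circle so they are not redundant with the FFT
#' family); bispectrum max/mean/sum over the principal domain with the two
#' bispectral entropies and the peak f1 coordinate; Wigner-bispectrum
#' max/mean/entropy, time-averaged diagonal max and diagonal peak frequency;
#' and diagonal Wigner-trispectrum max/mean/entropy. Constant input is valid:
#' every degenerate distribution maps to 0.
#'
#' @param s Single-axis numeric series (the window length; >= 16 samples).
#' @param fs Sampling rate, Hz.
#' @return Numeric vector of 34 finite values in registry order.
#' @export
extract_axis_features <- function(s, fs) {
  s <- as.numeric(s)
  n <- length(s)
  if (n < 16) abort_input("axis series too short for feature extraction")
  if (any(!is.finite(s))) abort_input("axis series contains non-finite values")
  prm <- hos_feature_params()
  ml <- min(prm$max_lag, (n - 1L) %/% 4L)
  sc <- s - mean(s)
  eps <- .Machine$double.eps * n

  ## time
  v_time <- c(max(s), min(s), max(s) - min(s), stats::var(s),
              hist_entropy_bits(s))

  ## fft
  X <- stats::fft(sc)
  half <- 0:(n %/% 2)
  f <- half * fs / n
  P <- Mod(X[half + 1])^2
  tot <- sum(P)
  if (tot <= eps) {
    v_fft <- numeric(6)
  } else {
    kmax <- which.max(P)
    v_fft <- c(f[kmax], sqrt(P[kmax]),
               sum(f * P) / tot, shannon_bits(P),
               sum(P[f <= 3]) / tot, sum(P[f > 3 & f <= 12]) / tot)
  }

  ## dct
  d <- dct_ii(sc)[-1]
  e <- d^2
  etot <- sum(e)
  v_dct <- c(abs(d[1:4]),
             if (etot <= eps) 0 else sum(e[seq_len(min(10, length(e)))]) / etot)

  ## zt (radius 0.95, fixed angles)
  angles <- pi * c(1 / 8, 1 / 4, 1 / 2, 3 / 4)
  j <- 0:(n - 1)
  v_zt <- vapply(angles, function(th)
    Mod(sum(sc * (0.95 * exp(1i * th))^(-j))), numeric(1))

  ## bispectrum over the principal domain
  bs <- bispectrum(sc, nfft = prm$nfft,
                   segment_len = min(prm$segment_len, n), fs = fs)
  mask <- bispectrum_principal_mask(bs)
  pv <- bs$values[mask]
  k1_mat <- matrix(rep(0:(nrow(bs$values) - 1L), times = ncol(bs$values)),
                   nrow(bs$values))
  peak_f1 <- if (max(pv) <= eps) 0 else {
    sel <- which(mask)[which.max(pv)]
    bs$f_axis[k1_mat[sel] + 1L]
  }
  v_bis <- c(max(pv), mean(pv), sum(pv), shannon_bits(pv), shannon_bits(pv^2),
             peak_f1)

  ## Wigner bispectrum (non-negative-frequency quadrant)
  wb <- wigner_bispectrum(sc, fs = fs, max_lag = ml,
                          time_decim = prm$time_decim)
  nf <- ml + 1L
  G <- wb$values[, 1:nf, 1:nf, drop = FALSE]
  Dg <- sapply(1:nf, function(k) wb$values[, k, k])
  Dg <- matrix(Dg, nrow = dim(wb$values)[1])
  prof <- colMeans(Dg)
  v_wb <- c(max(G), mean(G), shannon_bits(as.vector(G)),
            mean(apply(Dg, 1, max)),
            if (max(prof) <= eps) 0 else wb$f_axis[which.max(prof)])

  ## Wigner trispectrum diagonal
  wt <- wigner_trispectrum_diag(sc, fs = fs, max_lag = ml,
                                time_decim = prm$time_decim)
  Ht <- wt$values[, 1:nf, drop = FALSE]
  v_wt <- c(max(Ht), mean(Ht), shannon_bits(as.vector(Ht)))

  out <- c(v_time, v_fft, v_dct, v_zt, v_bis, v_wb, v_wt)
  if (any(!is.finite(out)))
    ws_abort("internal error: non-finite feature value", "ws_internal_error")
  out
}

#' Extract the full 102-element feature vector from a window
#'
#' Concatenates [extract_axis_features()] over the x, y, z axes in that order
#' and attaches the registry names; the class label (if any) travels along as
#' an attribute.
#'
#' @param w An `accel_window` from [segment_windows()].
#' @return Named numeric vector of length 102 with attributes `label` and
#'   `source`.
#' @export
extract_features <- function(w) {
  stopifnot(inherits(w, "accel_window"))
  vals <- unlist(lapply(c("x", "y", "z"), function(a) {
    tryCatch(extract_axis_features(w$samples[, a], w$fs),
             wearsense_error = function(e)
               abort_input(sprintf("axis %s: %s", a, conditionMessage(e))))
  }))
  names(vals) <- feature_registry()$name
  attr(vals, "label") <- w$label
  attr(vals, "source") <- w$source
  vals
}

#' Build the feature matrix for a list of windows
#'
#' @param windows Non-empty list of `accel_window` objects of uniform length.
#' @return List of class `feature_matrix` with `X` (n_windows x 102, columns
#'   in registry order, rows in input order), `labels`, `subjects`, and
#'   `registry_version`.
#' @export
feature_matrix <- function(windows) {
  if (!length(windows)) abort_input("no windows supplied")
  lens <- vapply(windows, function(w) nrow(w$samples), integer(1))
  if (length(unique(lens)) != 1L)
    abort_input("windows have mixed lengths; segment with a single window size")
  reg <- feature_registry()
  X <- t(vapply(windows, function(w) as.numeric(extract_features(w)),
                numeric(nrow(reg))))
  colnames(X) <- reg$name
  structure(
    list(X = X,
         labels = vapply(windows, function(w) w$label %||% NA_character_, ""),
         subjects = vapply(windows, function(w)
           w$source$subject_id %||% NA_character_, ""),
         registry_version = feature_registry_version()),
    class = "feature_matrix"
  )
}

#' Write a feature matrix as CSV with registry column headers
#'
#' @param fm A [feature_matrix()] result.
#' @param path Output path; a `label` column is appended when labels exist.
#' @export
write_feature_csv <- function(fm, path) {
  df <- as.data.frame(fm$X)
  if (!all(is.na(fm$labels))) df$label <- fm$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
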