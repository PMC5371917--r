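# Accelerometer recording I/O and fixed-length windowing.

#' Behavior class labels
#'
#' Canonical ordering of the three stereotypical-movement classes recognized
#' by the pipeline: sustained hand flapping, painting (drawing/writing), and
#' sibbing (self-hitting on the top of the head).
#'
#' @return Character vector of length 3.
#' @export
behavior_classes <- function() c("flapping", "painting", "sibbing")

# Maximum tolerated deviation of successive timestamp differences from the
# nominal sampling interval, as a fraction of that interval. Real smartwatch
# logs jitter; beyond this the file is rejected rather than regularized.
jitter_tolerance <- function(fs) 0.2 / fs

#' Construct a validated tri-axial accelerometer recording
#'
#' An `accel_recording` holds three equal-length acceleration series (m/s^2)
#' on a uniform time grid at sampling rate `fs`, plus an optional behavior
#' label and subject identifier. Timestamps must be strictly increasing with
#' per-step jitter at most `0.2/fs`; within tolerance they are regularized to
#' an exact uniform grid.
#'
#' @param ax,ay,az Numeric acceleration series for the x, y, z axes (m/s^2).
#' @param fs Sampling rate in Hz (default 50).
#' @param t Optional timestamps in seconds; defaults to a uniform grid.
#' @param label Optional class label, one of [behavior_classes()].
#' @param subject_id Opaque subject identifier string.
#' @return An object of class `accel_recording`.
#' @export
accel_recording <- function(ax, ay, az, fs = 50, t = NULL, label = NULL,
                            subject_id = NA_character_) {
  n <- length(ax)
  if (length(ay) != n || length(az) != n)
    abort_input("ax, ay, az must all have the same length")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    abort_input("fs must be a single positive number (Hz)")
  if (is.null(t)) {
    t <- if (n > 0) (seq_len(n) - 1) / fs else numeric(0)
  }
  if (length(t) != n)
    abort_input("t must have the same length as the axis series")
  if (n > 1) {
    dt <- diff(t)
    bad <- which(dt <= 0)
    if (length(bad))
      abort_quality(sprintf(
        "timestamps not strictly increasing at row %d", bad[1] + 1L))
    dev <- abs(dt - 1 / fs)
    tol <- jitter_tolerance(fs)
    bad <- which(dev > tol)
    if (length(bad))
      abort_quality(sprintf(
        "timestamp jitter %.4g s at row %d exceeds tolerance %.4g s (fs = %g Hz)",
        dev[bad[1]], bad[1] + 1L, tol, fs))
    t <- t[1] + (seq_len(n) - 1) / fs
  }
  if (!is.null(label)) label <- match.arg(label, behavior_classes())
  structure(
    list(t = as.numeric(t), ax = as.numeric(ax), ay = as.numeric(ay),
         az = as.numeric(az), fs = fs, label = label,
         subject_id = subject_id),
    class = "accel_recording"
  )
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> %d samples @ %g Hz (%.2f s)%s%s\n",
              length(x$t), x$fs,
              if (length(x$t)) length(x$t) / x$fs else 0,
              if (is.null(x$label)) "" else paste0(", label = ", x$label),
              if (is.na(x$subject_id)) "" else paste0(", subject = ", x$subject_id)))
  invisible(x)
}

#' @export
length.accel_recording <- function(x) length(x$t)

#' Read an accelerometer CSV recording
#'
#' Parses a comma-separated file with header `timestamp,x,y,z`. Timestamps are
#' seconds (float) or milliseconds (auto-detected when magnitudes exceed 1e6).
#' The series is validated against `fs_expected`: non-monotone timestamps or
#' jitter above `0.2/fs` reject the file with the first offending row named.
#'
#' @param path Path to a CSV file.
#' @param fs_expected Expected sampling rate in Hz (default 50).
#' @param label,subject_id Optional metadata attached to the recording
#'   (labels normally come from a dataset manifest, not from the file).
#' @return An [accel_recording()].
#' @export
read_accel_csv <- function(path, fs_expected = 50, label = NULL,
                           subject_id = NA_character_) {
  if (!file.exists(path))
    abort_input(sprintf("file not found: %s", path))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) abort_format(
                   sprintf("cannot parse %s as CSV: %s", path, conditionMessage(e))))
  required <- c("timestamp", "x", "y", "z")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    abort_format(sprintf("%s: missing required column(s): %s",
                         path, paste(missing_cols, collapse = ", ")))
  if (nrow(df) == 0)
    abort_input(sprintf("%s: empty recording (no data rows)", path))
  ts <- as.numeric(df$timestamp)
  if (anyNA(ts)) abort_format(sprintf("%s: non-numeric timestamp", path))
  if (max(abs(ts)) > 1e6) ts <- ts / 1000  # milliseconds -> seconds
  accel_recording(df$x, df$y, df$z, fs = fs_expected, t = ts,
                  label = label, subject_id = subject_id)
}

#' Write an accelerometer recording to CSV
#'
#' Writes the `timestamp,x,y,z` dialect read by [read_accel_csv()], preserving
#' values to 10 significant digits. An empty recording yields a header-only
#' file.
#'
#' @param rec An [accel_recording()].
#' @param path Output file path.
#' @export
write_accel_csv <- function(rec, path) {
  stopifnot(inherits(rec, "accel_recording"))
  lines <- "timestamp,x,y,z"
  if (length(rec$t))
    lines <- c(lines, sprintf("%.10g,%.10g,%.10g,%.10g",
                              rec$t, rec$ax, rec$ay, rec$az))
  tryCatch(writeLines(lines, path),
           error = function(e) abort_input(
             sprintf("cannot write %s: %s", path, conditionMessage(e))))
  invisible(path)
}

new_window <- function(samples, fs, label = NULL, subject_id = NA_character_,
                       start = NA_integer_) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L) abort_input("a window needs exactly 3 axis columns")
  if (any(!is.finite(samples))) abort_input("window contains missing values")
  colnames(samples) <- c("x", "y", "z")
  structure(
    list(samples = samples, fs = fs, label = label,
         source = list(subject_id = subject_id, start = start)),
    class = "accel_window"
  )
}

#' @export
print.accel_window <- function(x, ...) {
  cat(sprintf("<accel_window> %d x 3 @ %g Hz%s\n", nrow(x$samples), x$fs,
              if (is.null(x$label)) "" else paste0(", label = ", x$label)))
  invisible(x)
}

#' Segment a recording into fixed-length windows
#'
#' Cuts the recording into windows of `window_seconds * fs` samples with the
#' given fractional overlap; the trailing partial window is discarded. Windows
#' inherit the recording's label and subject id and record their start index.
#' The window count equals `floor((N - w) / step) + 1` with
#' `w = round(window_seconds * fs)` and `step = round(w * (1 - overlap))`.
#'
#' @param rec An [accel_recording()].
#' @param window_seconds Window length in seconds (default 2, i.e. 100 samples
#'   at 50 Hz).
#' @param overlap_fraction Fractional overlap in `[0, 1)` (default 0).
#' @return A list of `accel_window` objects; an empty list (with a warning)
#'   when the recording is shorter than one window.
#' @export
segment_windows <- function(rec, window_seconds = 2, overlap_fraction = 0) {
  stopifnot(inherits(rec, "accel_recording"))
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    abort_config("overlap_fraction must be in [0, 1)")
  w <- round(window_seconds * rec$fs)
  if (w < 4)
    abort_input("window_seconds * fs must be at least 4 samples")
  step <- max(1L, round(w * (1 - overlap_fraction)))
  n <- length(rec$t)
  if (n < w) {
    warning(sprintf(
      "recording of %d samples is shorter than one window (%d samples); no windows produced",
      n, w))
    return(list())
  }
  starts <- seq.int(1L, n - w + 1L, by = step)
  mat <- cbind(rec$ax, rec$ay, rec$az)
  lapply(starts, function(s)
    new_window(mat[s:(s + w - 1L), , drop = FALSE], fs = rec$fs,
               label = rec$label, subject_id = rec$subject_id, start = s))
}
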