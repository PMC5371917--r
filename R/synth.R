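# Synthetic motion generator for the three stereotypical-movement classes.
#
# The study's wrist recordings were never deposited, so these generative
# models stand in for them: they are invented motion models matched to the
# qualitative descriptions of each task, not biomechanical simulations.
# Gravity (9.81 m/s^2) is added on z and white Gaussian sensor noise on all
# axes for every class.

GRAVITY <- 9.81

#' Behavior simulation parameters
#'
#' Bundles the tunable knobs of one synthetic behavior class. For `flapping`
#' and `painting`, `base_freq` is the oscillation / tremor-centre frequency in
#' Hz; for `sibbing` it is the Poisson impact rate in events/s. `amplitude` is
#' the peak dynamic acceleration on the dominant axis in m/s^2.
#'
#' @param class_name One of [behavior_classes()].
#' @param base_freq Hz (flapping 3, painting 5, sibbing 1.5 events/s by
#'   default).
#' @param amplitude Peak acceleration, m/s^2 (defaults: flapping 8,
#'   painting 1.2, sibbing 12).
#' @param noise_sd Sensor noise standard deviation, m/s^2 (default 0.3).
#' @param subject_jitter Fractional per-subject perturbation applied to
#'   `base_freq` and `amplitude` by [generate_dataset()] (default 0.15).
#' @param seed RNG seed making the simulated recording reproducible.
#' @return A list of class `behavior_params`.
#' @export
behavior_params <- function(class_name, base_freq = NULL, amplitude = NULL,
                            noise_sd = 0.3, subject_jitter = 0.15, seed = 1L) {
  class_name <- match.arg(class_name, behavior_classes())
  defaults <- list(
    flapping = list(base_freq = 3,   amplitude = 8),
    painting = list(base_freq = 5,   amplitude = 1.2),
    sibbing  = list(base_freq = 1.5, amplitude = 12)
  )[[class_name]]
  base_freq <- base_freq %||% defaults$base_freq
  amplitude <- amplitude %||% defaults$amplitude
  if (base_freq <= 0) abort_config("base_freq must be positive")
  if (amplitude <= 0) abort_config("amplitude must be positive")
  if (noise_sd < 0) abort_config("noise_sd must be non-negative")
  structure(
    list(class_name = class_name, base_freq = base_freq, amplitude = amplitude,
         noise_sd = noise_sd, subject_jitter = subject_jitter,
         seed = as.integer(seed)),
    class = "behavior_params"
  )
}

# Dominant-axis flapping waveform: slow amplitude modulation times an
# antisymmetric fundamental + phase-locked 2nd harmonic, peak-normalized so
# `amplitude` is the true peak (noiseless peak-to-peak ~ 2 * amplitude).
flap_wave <- function(t, f0, amplitude, am_depth = 0.3, am_freq = 0.3) {
  phi <- stats::runif(1, 0, 2 * pi)
  am_phi <- stats::runif(1, 0, 2 * pi)
  theta <- 2 * pi * f0 * t + phi
  env <- 1 + am_depth * sin(2 * pi * am_freq * t + am_phi)
  core <- env * (sin(theta) + 0.3 * sin(2 * theta))
  amplitude * core / max(abs(core))
}

paint_axis <- function(t, f_tremor, amplitude, tremor_rel) {
  drift <- 0
  for (i in 1:4) {
    fi <- stats::runif(1, 0.1, 1.5)
    ai <- amplitude * stats::runif(1, 0.3, 1) / i
    drift <- drift + ai * sin(2 * pi * fi * t + stats::runif(1, 0, 2 * pi))
  }
  tremor <- tremor_rel * amplitude *
    sin(2 * pi * stats::runif(1, 0.9, 1.1) * f_tremor * t + stats::runif(1, 0, 2 * pi))
  drift + tremor
}

sib_impacts <- function(t, duration, rate, amplitude, decay = 0.06) {
  n_ev <- stats::rpois(1, rate * duration)
  s <- numeric(length(t))
  if (n_ev > 0) {
    times <- sort(stats::runif(n_ev, 0, duration))
    amps <- amplitude * stats::runif(n_ev, 0.7, 1.3)
    for (k in seq_len(n_ev)) {
      dt <- t - times[k]
      on <- dt >= 0
      s[on] <- s[on] + amps[k] * exp(-dt[on] / decay)
    }
  }
  s
}

#' Simulate one behavior recording
#'
#' Generative models: *flapping* is a quasi-periodic oscillation at
#' `base_freq` with a phase-locked 2x harmonic, amplitude-modulated at 0.3 Hz,
#' dominant on the x and z axes; *painting* is low-frequency (< 1.5 Hz)
#' multi-sine drift plus a small 4-6 Hz tremor, dominant on x/y; *sibbing* is
#' a Poisson train (rate `base_freq` events/s) of exponentially decaying
#' impacts on z over a quiet baseline. All classes add gravity on z and white
#' Gaussian noise of sd `noise_sd` on every axis. Deterministic given
#' `params$seed`.
#'
#' @param params A [behavior_params()] object.
#' @param duration Recording length in seconds (default 20, at least one
#'   analysis window).
#' @param fs Sampling rate in Hz (default 50); `base_freq` must stay below
#'   the Nyquist rate `fs/2`.
#' @param subject_id Subject tag carried into the recording.
#' @return An [accel_recording()] carrying the class label.
#' @export
simulate_behavior <- function(params, duration = 20, fs = 50,
                              subject_id = NA_character_) {
  stopifnot(inherits(params, "behavior_params"))
  if (params$class_name != "sibbing" && params$base_freq >= fs / 2)
    abort_config(sprintf("base_freq %g Hz is not below Nyquist (%g Hz)",
                         params$base_freq, fs / 2))
  n <- round(duration * fs)
  if (n < 4) abort_config("duration too short")
  t <- (seq_len(n) - 1) / fs
  A <- params$amplitude
  sig <- with_seed(params$seed, {
    core <- switch(params$class_name,
      flapping = {
        x <- flap_wave(t, params$base_freq, A)
        z <- flap_wave(t, params$base_freq, 0.9 * A)
        y <- flap_wave(t, params$base_freq, 0.25 * A)
        cbind(x, y, z)
      },
      painting = {
        # tremor prominence varies strongly between writers
        trem <- stats::runif(1, 0.1, 0.45)
        x <- paint_axis(t, params$base_freq, A, trem)
        y <- paint_axis(t, params$base_freq, 0.8 * A, trem)
        z <- paint_axis(t, params$base_freq, 0.4 * A, trem)
        cbind(x, y, z)
      },
      sibbing = {
        z <- sib_impacts(t, duration, params$base_freq, A)
        x <- 0.2 * sib_impacts(t, duration, params$base_freq, A)
        y <- 0.15 * sib_impacts(t, duration, params$base_freq, A)
        cbind(x, y, z)
      })
    core + matrix(stats::rnorm(3 * n, 0, params$noise_sd), n, 3)
  })
  accel_recording(sig[, 1], sig[, 2], sig[, 3] + GRAVITY, fs = fs,
                  label = params$class_name, subject_id = subject_id)
}

#' Generate a balanced synthetic dataset
#'
#' Produces `n_per_class` recordings per class, interleaved class-by-class and
#' assigned round-robin to `n_subjects` synthetic subjects. Each subject gets
#' a fixed fractional jitter (uniform in +/- `subject_jitter`) on base
#' frequency and amplitude, emulating individual variation between
#' participants. On top of that, every recording draws its own
#' frequency/rate and amplitude factors from class-specific ranges (flapping
#' tempo 0.75-1.5x and amplitude 0.25-1.4x, painting amplitude 0.4-2.5x,
#' sibbing rate 0.55-1.65x and amplitude 0.4-1.3x), so the classes overlap
#' in amplitude and band occupancy rather than being separable by a single
#' threshold. Per-recording RNG streams are derived from `seed` and a
#' counter, so a recording's samples never depend on how many recordings
#' follow it.
#'
#' @param n_per_class Recordings per class (default 55, giving 165 total for
#'   the three classes).
#' @param duration Seconds per recording (default 20).
#' @param fs Sampling rate, Hz.
#' @param n_subjects Number of synthetic subjects (default 14).
#' @param seed RNG seed; the full dataset is bit-identical across runs for a
#'   fixed seed.
#' @param classes Class names to generate.
#' @param noise_sd,subject_jitter Passed to [behavior_params()].
#' @return A list of [accel_recording()] objects.
#' @export
generate_dataset <- function(n_per_class = 55, duration = 20, fs = 50,
                             n_subjects = 14, seed = 7,
                             classes = behavior_classes(),
                             noise_sd = 0.3, subject_jitter = 0.15) {
  if (n_per_class < 1 || n_subjects < 1) abort_config("counts must be positive")
  classes <- vapply(classes, match.arg, "", choices = behavior_classes())
  n_total <- n_per_class * length(classes)
  draws <- with_seed(seed, {
    jit <- matrix(stats::runif(2 * n_subjects, -subject_jitter,
                               subject_jitter), n_subjects, 2)
    list(jit = jit, u = matrix(stats::runif(2 * n_total), n_total, 2))
  })
  # class-specific per-recording variation ranges (freq-or-rate, amplitude)
  style_range <- list(
    flapping = list(freq = c(0.75, 1.5), amp = c(0.25, 1.4)),
    painting = list(freq = c(0.8, 1.2),  amp = c(0.4, 2.5)),
    sibbing  = list(freq = c(0.55, 1.65), amp = c(0.4, 1.3))
  )
  recs <- vector("list", n_total)
  counter <- 0L
  for (i in seq_len(n_per_class)) {
    for (cl in classes) {
      counter <- counter + 1L
      subj <- ((counter - 1L) %% n_subjects) + 1L
      rec_seed <- (as.integer(seed) + 7919L * counter) %% 2147483647L
      p <- behavior_params(cl, noise_sd = noise_sd,
                           subject_jitter = subject_jitter, seed = rec_seed)
      rng <- style_range[[cl]]
      f_fac <- rng$freq[1] + draws$u[counter, 1] * diff(rng$freq)
      a_fac <- rng$amp[1] + draws$u[counter, 2] * diff(rng$amp)
      p$base_freq <- p$base_freq * f_fac * (1 + draws$jit[subj, 1])
      p$amplitude <- p$amplitude * a_fac * (1 + draws$jit[subj, 2])
      recs[[counter]] <- simulate_behavior(p, duration = duration, fs = fs,
                                           subject_id = sprintf("S%02d", subj))
    }
  }
  recs
}

#' Write a dataset directory (one CSV per recording plus a manifest)
#'
#' @param recs List of recordings, e.g. from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Path of the manifest CSV (`filename,class,subject`), invisibly.
#' @export
write_dataset <- function(recs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(recs), function(i) {
    fname <- sprintf("rec_%04d.csv", i)
    write_accel_csv(recs[[i]], file.path(dir, fname))
    data.frame(filename = fname,
               class = recs[[i]]$label %||% NA_character_,
               subject = recs[[i]]$subject_id,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' Read a dataset directory via its manifest
#'
#' @param dir Directory containing recordings and `manifest.csv`
#'   (`filename,class,subject`); labels come from the manifest, never from
#'   file names.
#' @param manifest_path Manifest location (default `dir/manifest.csv`).
#' @param fs_expected Sampling rate passed to [read_accel_csv()].
#' @return List of labelled [accel_recording()] objects.
#' @export
read_dataset <- function(dir, manifest_path = file.path(dir, "manifest.csv"),
                         fs_expected = 50) {
  if (!file.exists(manifest_path))
    abort_input(sprintf("no recordings found: missing manifest %s", manifest_path))
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("filename", "class", "subject")
  if (!all(need %in% names(manifest)))
    abort_format("manifest must have columns filename, class, subject")
  if (nrow(manifest) == 0) abort_input("no recordings found: manifest is empty")
  lapply(seq_len(nrow(manifest)), function(i) {
    read_accel_csv(file.path(dir, manifest$filename[i]),
                   fs_expected = fs_expected,
                   label = manifest$class[i],
                   subject_id = as.character(manifest$subject[i]))
  })
}
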