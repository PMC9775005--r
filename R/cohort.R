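# Synthetic multi-subject cohort generator.
#
# Emulates three-channel prefrontal (Fp1, Fpz, Fp2) resting-state EEG with
# class structure (reduced alpha power, elevated theta/alpha ratio in the
# depressed class) and per-subject random effects (gain, baseline offset,
# noise level, alpha peak shift) that create between-subject distribution
# shift, plus 50 Hz mains contamination.

# Fixed 3x3 mixing of shared sources (columns: alpha, theta, pink floor)
# into the three channels. Neighbouring prefrontal electrodes are strongly
# correlated, so the rows are close but not identical.
.MIXING <- matrix(
  c(1.00, 0.85, 0.90,
    0.92, 1.00, 0.95,
    0.96, 0.90, 1.00),
  nrow = 3, byrow = TRUE,
  dimnames = list(CHANNEL_NAMES, c("alpha", "theta", "pink"))
)

#' Subject profile for the synthetic EEG generator
#'
#' Bundles the per-subject parameters that drive signal synthesis: the class
#' label, an amplitude gain, a DC baseline offset, the noise-floor level, the
#' individual alpha peak frequency, band powers and mains contamination
#' amplitude, plus the seed of the subject's private random stream.
#'
#' @param subject_id Character identifier.
#' @param label Class label, one of `"healthy"` or `"depressed"`.
#' @param gain Positive amplitude multiplier applied to the neural sources.
#' @param baseline_offset DC offset in microvolts.
#' @param noise_sd Noise-floor level in microvolts; split equally in variance
#'   between a shared 1/f (pink) floor and per-channel white noise, so
#'   `noise_sd = 0` yields a noiseless signal.
#' @param alpha_peak_hz Individual alpha peak frequency in Hz, in \[8, 13\].
#' @param alpha_power Alpha band power in squared microvolts.
#' @param theta_power Theta band power in squared microvolts.
#' @param mains_amplitude Amplitude of the 50 Hz mains component, microvolts.
#' @param seed Integer seed of the subject's random stream; generation is
#'   bit-reproducible given the profile.
#'
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, label,
                            gain = 1, baseline_offset = 0, noise_sd = 3,
                            alpha_peak_hz = 10.5, alpha_power = 25,
                            theta_power = 9, mains_amplitude = 5,
                            seed = 1L) {
  label <- match.arg(label, CLASS_LEVELS)
  check_scalar(gain, "gain", positive = TRUE)
  check_scalar(baseline_offset, "baseline_offset")
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(alpha_peak_hz, "alpha_peak_hz")
  if (alpha_peak_hz < 8 || alpha_peak_hz > 13) {
    stop_invalid("`alpha_peak_hz` must lie in [8, 13]")
  }
  check_scalar(alpha_power, "alpha_power", nonneg = TRUE)
  check_scalar(theta_power, "theta_power", nonneg = TRUE)
  check_scalar(mains_amplitude, "mains_amplitude", nonneg = TRUE)
  check_scalar(seed, "seed")
  structure(
    list(subject_id = as.character(subject_id), label = label, gain = gain,
         baseline_offset = baseline_offset, noise_sd = noise_sd,
         alpha_peak_hz = alpha_peak_hz, alpha_power = alpha_power,
         theta_power = theta_power, mains_amplitude = mains_amplitude,
         seed = as.integer(seed)),
    class = "subject_profile"
  )
}

#' Construct a labelled three-channel EEG recording
#'
#' @param subject_id Character identifier.
#' @param label `"healthy"` or `"depressed"`.
#' @param samples 3 x T numeric matrix (microvolts), rows Fp1, Fpz, Fp2.
#' @param fs Sampling rate in Hz.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(subject_id, label, samples, fs = 250) {
  label <- match.arg(label, CLASS_LEVELS)
  check_scalar(fs, "fs", positive = TRUE)
  if (!is.matrix(samples) || nrow(samples) != 3L) {
    stop_invalid("`samples` must be a 3 x T matrix (Fp1, Fpz, Fp2)")
  }
  if (ncol(samples) < fs) {
    stop_invalid("recording must contain at least one second of data")
  }
  rownames(samples) <- CHANNEL_NAMES
  structure(
    list(subject_id = as.character(subject_id), label = label,
         channels = CHANNEL_NAMES, samples = samples, fs = fs),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s]: 3 x %d samples @ %g Hz\n",
              x$subject_id, x$label, ncol(x$samples), x$fs))
  invisible(x)
}

# Narrow-band stochastic oscillation: band-pass filtered white noise,
# rescaled to the requested power (variance). Returns zeros when power = 0
# without consuming random numbers.
.band_component <- function(n, fs, center_hz, half_width_hz, power) {
  if (power <= 0) return(numeric(n))
  lo <- max(center_hz - half_width_hz, 0.1)
  hi <- min(center_hz + half_width_hz, fs / 2 - 0.1)
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  y <- signal::filter(bf, stats::rnorm(n))
  y <- as.numeric(y)
  y <- y - mean(y)
  s <- stats::sd(y)
  if (s == 0) return(numeric(n))
  y * sqrt(power) / s
}

# 1/f-amplitude (pink) noise via spectral shaping of white noise,
# normalized to unit standard deviation. Returns zeros when n too short.
.pink_noise <- function(n) {
  if (n < 4L) return(numeric(n))
  wh <- stats::rnorm(n)
  k <- 0:(n - 1)
  fk <- pmin(k, n - k)
  amp <- ifelse(fk == 0, 0, 1 / sqrt(fk))
  y <- Re(stats::fft(stats::fft(wh) * amp, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(numeric(n))
  y / s
}

#' Generate one subject's synthetic EEG recording
#'
#' Synthesizes a 3 x T recording from a [subject_profile()]: shared alpha,
#' theta and pink-noise sources mixed into the three channels by a fixed
#' mixing matrix (so the channels are correlated but not identical), scaled
#' by the subject gain, plus baseline offset, 50 Hz mains contamination and
#' per-channel white noise. Bit-reproducible given the profile (which
#' carries its own seed).
#'
#' @param profile A [subject_profile()].
#' @param duration_s Recording length in seconds; `T = floor(duration_s * fs)`.
#' @param fs Sampling rate in Hz (default 250).
#' @return An [recording()] of `floor(duration_s * fs)` samples.
#' @export
generate_subject <- function(profile, duration_s, fs = 250) {
  if (!inherits(profile, "subject_profile")) {
    stop_invalid("`profile` must be a subject_profile")
  }
  check_scalar(duration_s, "duration_s", positive = TRUE)
  check_scalar(fs, "fs", positive = TRUE)
  n <- floor(duration_s * fs)
  if (n < 1) stop_invalid("duration_s * fs must be at least 1")
  t <- (seq_len(n) - 1) / fs

  with_seed(profile$seed, {
    alpha <- .band_component(n, fs, profile$alpha_peak_hz, 1.0,
                             profile$alpha_power)
    theta <- .band_component(n, fs, 6, 2.0, profile$theta_power)
    pink_sd <- profile$noise_sd / sqrt(2)
    pink <- if (pink_sd > 0) pink_sd * .pink_noise(n) else numeric(n)
    mains <- if (profile$mains_amplitude > 0) {
      profile$mains_amplitude * sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi))
    } else {
      numeric(n)
    }
    sources <- rbind(alpha, theta, pink)
    mixed <- .MIXING %*% sources
    white_sd <- profile$noise_sd / sqrt(2)
    samples <- profile$gain * mixed + profile$baseline_offset
    samples <- sweep(samples, 2, mains, `+`)
    if (white_sd > 0) {
      samples <- samples + matrix(stats::rnorm(3 * n, sd = white_sd), nrow = 3)
    }
    recording(profile$subject_id, profile$label, samples, fs)
  })
}

#' Generate a labelled multi-subject cohort with controlled domain shift
#'
#' Draws one [subject_profile()] per subject and synthesizes its recording.
#' The depressed class has its log band powers displaced by `class_effect`
#' standard deviations (alpha down, theta up); per-subject gain, baseline,
#' noise level and alpha peak frequency are drawn with dispersion `shift_sd`,
#' creating between-subject distribution shift. Each subject owns a private
#' random stream derived from `(seed, subject index)`, so enlarging the
#' cohort never perturbs existing subjects.
#'
#' @param n_healthy,n_depressed Nonnegative subject counts.
#' @param class_effect Standardized mean shift between class band-power
#'   distributions; 0 makes the classes identically distributed.
#' @param shift_sd Dispersion of the per-subject nuisance parameters
#'   (log-scale sd for gain and noise level; scales the baseline-offset and
#'   alpha-peak sds).
#' @param seed Integer cohort seed.
#' @param duration_s Per-recording duration in seconds (default 60).
#' @param fs Sampling rate in Hz (default 250).
#' @return A list of [recording()] objects, healthy subjects first.
#' @export
generate_cohort <- function(n_healthy, n_depressed, class_effect = 1,
                            shift_sd = 0.3, seed = 1L,
                            duration_s = 60, fs = 250) {
  if (!is.numeric(n_healthy) || !is.numeric(n_depressed) ||
      n_healthy < 0 || n_depressed < 0) {
    stop_invalid("subject counts must be nonnegative")
  }
  check_scalar(class_effect, "class_effect")
  check_scalar(shift_sd, "shift_sd", nonneg = TRUE)
  n_healthy <- as.integer(n_healthy)
  n_depressed <- as.integer(n_depressed)
  labels <- rep(CLASS_LEVELS, c(n_healthy, n_depressed))
  n_total <- n_healthy + n_depressed
  if (n_total == 0L) return(list())

  # Healthy-class centers of the log band-power distributions; the class
  # effect moves the depressed means in units of these log-scale sds.
  log_alpha_mu <- log(25); log_alpha_sd <- 0.25
  log_theta_mu <- log(9);  log_theta_sd <- 0.25

  cohort <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    subj_seed <- derive_seed(seed, i)
    dep <- labels[i] == "depressed"
    prof <- with_seed(subj_seed, {
      a_mu <- log_alpha_mu - if (dep) class_effect * log_alpha_sd else 0
      t_mu <- log_theta_mu + if (dep) class_effect * log_theta_sd else 0
      alpha_power <- exp(stats::rnorm(1, a_mu, log_alpha_sd))
      theta_power <- exp(stats::rnorm(1, t_mu, log_theta_sd))
      gain <- exp(stats::rnorm(1, 0, shift_sd))
      baseline <- stats::rnorm(1, 0, 10 * shift_sd)
      noise_sd <- 3 * exp(stats::rnorm(1, 0, shift_sd))
      alpha_peak <- min(13, max(8, stats::rnorm(1, 10.5, 3 * shift_sd)))
      mains <- 5 * exp(stats::rnorm(1, 0, shift_sd / 2))
      signal_seed <- sample.int(2147483646L, 1)
      subject_profile(
        subject_id = sprintf("S%03d_%s", i, if (dep) "dep" else "hc"),
        label = labels[i], gain = gain, baseline_offset = baseline,
        noise_sd = noise_sd, alpha_peak_hz = alpha_peak,
        alpha_power = alpha_power, theta_power = theta_power,
        mains_amplitude = mains, seed = signal_seed
      )
    })
    cohort[[i]] <- generate_subject(prof, duration_s, fs)
  }
  cohort
}

#' Write a cohort to the plain-text per-recording layout
#'
#' Emits one delimited text file per recording (columns Fp1, Fpz, Fp2, one
#' row per sample, single header line) and a cohort manifest CSV with
#' columns `subject_id, label, file, fs`.
#'
#' @param cohort List of [recording()] objects.
#' @param dir Output directory (created if needed).
#' @param delim Column delimiter, `","` (default) or whitespace `" "`.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir, delim = ",") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(length(cohort))
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]
    f <- file.path(dir, paste0(rec$subject_id, ".txt"))
    df <- as.data.frame(t(rec$samples))
    names(df) <- CHANNEL_NAMES
    utils::write.table(df, f, sep = delim, row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
    files[i] <- f
  }
  manifest <- data.frame(
    subject_id = vapply(cohort, `[[`, "", "subject_id"),
    label = vapply(cohort, `[[`, "", "label"),
    file = basename(files),
    fs = vapply(cohort, `[[`, 0, "fs"),
    stringsAsFactors = FALSE
  )
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' Read one recording from the plain-text layout
#'
#' Accepts comma- or whitespace-delimited numeric columns Fp1, Fpz, Fp2 with
#' an optional single header line.
#'
#' @param file Path to the text file.
#' @param subject_id,label,fs Recording metadata.
#' @return An [recording()].
#' @export
read_recording <- function(file, subject_id, label, fs = 250) {
  first <- readLines(file, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  sep <- if (grepl(",", first)) "," else ""
  df <- utils::read.table(file, header = has_header, sep = sep)
  if (ncol(df) != 3L) stop_invalid("expected 3 numeric columns, got ", ncol(df))
  recording(subject_id, label, t(as.matrix(df)), fs)
}

#' Read a cohort back from its manifest
#'
#' @param manifest Path to a manifest CSV written by [write_cohort()].
#' @return A list of [recording()] objects.
#' @export
read_cohort <- function(manifest) {
  m <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  lapply(seq_len(nrow(m)), function(i) {
    read_recording(file.path(dir, m$file[i]), m$subject_id[i],
                   m$label[i], m$fs[i])
  })
}
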