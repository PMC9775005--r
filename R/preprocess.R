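# Signal chain: per-channel min-max normalization, 30-70% core-segment
# selection, Butterworth high-pass / mains-notch / band-pass cascade, and
# one-second (250-sample) windowing.
#
# Coordinate conventions, used everywhere: 0-based sample indices, half-open
# intervals [start, start + L), floor for fractional positions.

#' Filter-chain specification
#'
#' Three Butterworth stages applied in order: high-pass (removes drift and
#' DC), band-stop over the mains band, band-pass restricting to the
#' physiological range. Each stage is applied per channel; with
#' `zero_phase = TRUE` (default) stages run forward-backward so the filtered
#' waveform stays aligned with the input, at the cost of doubling the
#' effective order.
#'
#' @param highpass_cutoff_hz High-pass cutoff in Hz (default 1).
#' @param notch_band_hz Length-2 stop band in Hz (default `c(48, 52)`).
#' @param bandpass_band_hz Length-2 pass band in Hz (default `c(0.5, 35)`).
#' @param highpass_order,notch_order,bandpass_order Butterworth orders per
#'   stage (defaults 4, 2, 4).
#' @param zero_phase Apply each stage forward-backward (default `TRUE`).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(highpass_cutoff_hz = 1,
                        notch_band_hz = c(48, 52),
                        bandpass_band_hz = c(0.5, 35),
                        highpass_order = 4L, notch_order = 2L,
                        bandpass_order = 4L, zero_phase = TRUE) {
  check_scalar(highpass_cutoff_hz, "highpass_cutoff_hz", positive = TRUE)
  for (b in list(notch_band_hz, bandpass_band_hz)) {
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2] || b[1] <= 0) {
      stop_invalid("band intervals must be increasing positive length-2 vectors")
    }
  }
  for (o in c(highpass_order, notch_order, bandpass_order)) {
    if (o < 1) stop_invalid("filter orders must be >= 1")
  }
  structure(
    list(highpass_cutoff_hz = highpass_cutoff_hz,
         notch_band_hz = notch_band_hz,
         bandpass_band_hz = bandpass_band_hz,
         highpass_order = as.integer(highpass_order),
         notch_order = as.integer(notch_order),
         bandpass_order = as.integer(bandpass_order),
         zero_phase = isTRUE(zero_phase)),
    class = "filter_spec"
  )
}

#' Per-channel min-max normalization to \[0, 1\]
#'
#' Applies `x' = (x - min) / (max - min)` independently to each row. A
#' constant channel has no well-defined scale and raises a degenerate-input
#' error identifying the channel rather than silently emitting a constant.
#'
#' @param samples channel x T numeric matrix.
#' @return Matrix of the same shape with every row in \[0, 1\].
#' @export
minmax_normalize <- function(samples) {
  if (!is.matrix(samples) || ncol(samples) < 1L) {
    stop_invalid("`samples` must be a matrix with at least one column")
  }
  mins <- apply(samples, 1, min)
  maxs <- apply(samples, 1, max)
  flat <- which(maxs == mins)
  if (length(flat) > 0) {
    nm <- rownames(samples)[flat[1]]
    if (is.null(nm)) nm <- as.character(flat[1])
    stop_degenerate("constant channel cannot be min-max normalized: ", nm)
  }
  (samples - mins) / (maxs - mins)
}

#' Select the core segment of a recording
#'
#' Retains samples with 0-based indices in `[floor(lo * T), floor(hi * T))`,
#' discarding the start and end of the recording where resting-state data
#' are least representative. Defaults to the central 30%-70% span.
#'
#' @param samples channel x T numeric matrix.
#' @param core_fraction Length-2 vector `c(lo, hi)` with `0 <= lo < hi <= 1`.
#' @return channel x T' matrix, `T' = floor(hi * T) - floor(lo * T)`.
#' @export
select_core_segment <- function(samples, core_fraction = c(0.30, 0.70)) {
  if (!is.matrix(samples)) stop_invalid("`samples` must be a matrix")
  lo <- core_fraction[1]; hi <- core_fraction[2]
  if (!(lo >= 0 && lo < hi && hi <= 1)) {
    stop_invalid("`core_fraction` must satisfy 0 <= lo < hi <= 1")
  }
  n <- ncol(samples)
  from <- floor(lo * n)        # 0-based inclusive
  to <- floor(hi * n)          # 0-based exclusive
  if (to - from < 1L) {
    stop_degenerate("core segment is empty for T = ", n)
  }
  samples[, (from + 1L):to, drop = FALSE]
}

# Second-order-section-free realization: signal::butter coefficient form.
.stage_filters <- function(spec, fs) {
  nyq <- fs / 2
  if (spec$highpass_cutoff_hz >= nyq ||
      spec$notch_band_hz[2] >= nyq ||
      spec$bandpass_band_hz[2] >= nyq) {
    stop_invalid("sampling rate too low for the requested filter bands")
  }
  list(
    signal::butter(spec$highpass_order, spec$highpass_cutoff_hz / nyq,
                   type = "high"),
    signal::butter(spec$notch_order, spec$notch_band_hz / nyq, type = "stop"),
    signal::butter(spec$bandpass_order, spec$bandpass_band_hz / nyq,
                   type = "pass")
  )
}

#' Apply the three-stage filter cascade
#'
#' High-pass, mains band-stop and band-pass Butterworth stages applied in
#' order, independently per channel. Output length equals input length.
#'
#' @param samples channel x T numeric matrix.
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered channel x T matrix.
#' @export
apply_filter_chain <- function(samples, fs, spec = filter_spec()) {
  if (!is.matrix(samples)) stop_invalid("`samples` must be a matrix")
  check_scalar(fs, "fs", positive = TRUE)
  if (!inherits(spec, "filter_spec")) stop_invalid("`spec` must be a filter_spec")
  max_order <- max(spec$highpass_order, spec$notch_order * 2L,
                   spec$bandpass_order * 2L)
  if (ncol(samples) <= 3L * max_order) {
    stop_invalid("too few samples (", ncol(samples), ") for the filter orders")
  }
  filts <- .stage_filters(spec, fs)
  out <- samples
  for (ch in seq_len(nrow(out))) {
    x <- out[ch, ]
    for (bf in filts) {
      x <- if (spec$zero_phase) signal::filtfilt(bf, x)
           else as.numeric(signal::filter(bf, x))
    }
    out[ch, ] <- x
  }
  out
}

#' Analytic magnitude response of the composed cascade
#'
#' Product of the three stages' transfer-function magnitudes at the given
#' frequencies; with `zero_phase` filtering each magnitude is squared. Used
#' as the independent oracle for the measured steady-state gain.
#'
#' @param freqs_hz Frequencies in Hz (below Nyquist).
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Numeric vector of linear gains.
#' @export
filter_chain_response <- function(freqs_hz, fs, spec = filter_spec()) {
  filts <- .stage_filters(spec, fs)
  w <- 2 * pi * freqs_hz / fs
  gain <- rep(1, length(w))
  for (bf in filts) {
    h <- vapply(w, function(wi) {
      z <- exp(-1i * wi)
      num <- sum(bf$b * z^(seq_along(bf$b) - 1))
      den <- sum(bf$a * z^(seq_along(bf$a) - 1))
      Mod(num / den)
    }, numeric(1))
    if (spec$zero_phase) h <- h^2
    gain <- gain * h
  }
  gain
}

#' Cut contiguous non-overlapping windows
#'
#' Produces `floor(T' / window_len)` windows of exactly `window_len` samples
#' per channel; the trailing remainder is discarded. Too-short input yields
#' an empty window set (with a message), not an error.
#'
#' @param samples channel x T' numeric matrix.
#' @param window_len Window length in samples (default 250, one second at
#'   250 Hz).
#' @param subject_id,label Optional provenance carried on the result.
#' @return An object of class `window_set`: list with `windows` (list of
#'   channel x window_len matrices), `window_len`, `subject_id`, `label`.
#' @export
segment_windows <- function(samples, window_len = 250L,
                            subject_id = NA_character_,
                            label = NA_character_) {
  if (!is.matrix(samples)) stop_invalid("`samples` must be a matrix")
  if (window_len < 1) stop_invalid("`window_len` must be >= 1")
  window_len <- as.integer(window_len)
  n_win <- ncol(samples) %/% window_len
  if (n_win == 0L) {
    message(sprintf("segment_windows: %d samples < window_len %d; empty window set",
                    ncol(samples), window_len))
  }
  windows <- vector("list", n_win)
  for (k in seq_len(n_win)) {
    idx <- ((k - 1L) * window_len + 1L):(k * window_len)
    windows[[k]] <- samples[, idx, drop = FALSE]
  }
  structure(
    list(subject_id = subject_id, label = label, windows = windows,
         window_len = window_len),
    class = "window_set"
  )
}

#' Preprocessing configuration
#'
#' @param filter A [filter_spec()].
#' @param core_fraction Core-segment fraction interval (default
#'   `c(0.30, 0.70)`).
#' @param window_len Window length in samples (default 250).
#' @param normalize_first Normalize before filtering (default `TRUE`,
#'   mirroring the order in which the steps are usually narrated); set
#'   `FALSE` to normalize after the cascade instead.
#' @param filter_whole_segment Filter the entire core segment once before
#'   windowing (default `TRUE`); `FALSE` filters each 1-s window separately,
#'   which introduces per-window edge transients and exists for fidelity
#'   experiments only.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(filter = filter_spec(),
                              core_fraction = c(0.30, 0.70),
                              window_len = 250L,
                              normalize_first = TRUE,
                              filter_whole_segment = TRUE) {
  structure(
    list(filter = filter, core_fraction = core_fraction,
         window_len = as.integer(window_len),
         normalize_first = isTRUE(normalize_first),
         filter_whole_segment = isTRUE(filter_whole_segment)),
    class = "preprocess_config"
  )
}

#' Run the full preprocessing chain on one recording
#'
#' Normalize (per channel, per recording), select the core segment, apply
#' the filter cascade to the whole segment, and cut 1-s windows. See
#' [preprocess_config()] for the two order variants.
#'
#' @param rec An [recording()].
#' @param config A [preprocess_config()].
#' @return A `window_set` of filtered windows.
#' @export
preprocess_recording <- function(rec, config = preprocess_config()) {
  if (!inherits(rec, "eeg_recording")) stop_invalid("`rec` must be an eeg_recording")
  x <- rec$samples
  if (config$normalize_first) x <- minmax_normalize(x)
  x <- select_core_segment(x, config$core_fraction)
  if (config$filter_whole_segment) {
    x <- apply_filter_chain(x, rec$fs, config$filter)
    if (!config$normalize_first) x <- minmax_normalize(x)
    ws <- segment_windows(x, config$window_len, rec$subject_id, rec$label)
  } else {
    ws <- segment_windows(x, config$window_len, rec$subject_id, rec$label)
    ws$windows <- lapply(ws$windows, function(w) {
      w <- apply_filter_chain(w, rec$fs, config$filter)
      if (!config$normalize_first) w <- minmax_normalize(w)
      w
    })
  }
  ws
}
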