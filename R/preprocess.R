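# Preprocessing: band-pass -> normalize -> notch -> segment.
#
# Filters are applied forward-backward (zero phase) so cue-locked epoch
# timing is preserved; the band-pass is a Butterworth IIR design (the
# standard choice for extracting the mu/beta rhythms) and the notch is a
# second-order biquad.

.apply_zero_phase <- function(recording, b, a, stage) {
  out <- recording$data
  for (i in seq_len(nrow(out))) {
    y <- signal::filtfilt(signal::Arma(b = b, a = a), out[i, ])
    if (any(!is.finite(y)))
      stop_mibci("numeric", "%s filter unstable on channel %s", stage,
                 recording$channel_labels[i])
    out[i, ] <- y
  }
  eeg_recording(out, recording$fs, recording$channel_labels, recording$markers)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Extracts the mu/beta rhythm range (default 10-30 Hz) from every channel
#' with a Butterworth band-pass applied forward and backward, so the output
#' has zero group delay.
#'
#' @param recording an [eeg_recording()].
#' @param low_hz,high_hz passband edges in Hz (0 < low < high < fs/2).
#' @param order filter order (default 5).
#' @return filtered [eeg_recording()].
#' @export
bandpass_filter <- function(recording, low_hz = 10, high_hz = 30, order = 5L) {
  stopifnot(inherits(recording, "eeg_recording"))
  nyq <- recording$fs / 2
  if (!is_num1(low_hz) || !is_num1(high_hz) || low_hz <= 0 || low_hz >= high_hz)
    stop_mibci("parameter", "need 0 < low_hz < high_hz")
  if (high_hz >= nyq)
    stop_mibci("parameter", "high_hz (%g) must be below the Nyquist frequency (%g)",
               high_hz, nyq)
  if (!is_count(order)) stop_mibci("parameter", "order must be a positive integer")
  bw <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  .apply_zero_phase(recording, bw$b, bw$a, "band-pass")
}

#' Per-channel z-score normalization
#'
#' Removes absolute amplitude differences between channels: each channel is
#' centered on its mean and divided by its population standard deviation,
#' computed over the full continuous recording (before segmentation).
#'
#' @param recording an [eeg_recording()].
#' @return list with `recording` (normalized copy) and `params` (data frame
#'   of per-channel `mean` and `sd`).
#' @export
zscore_normalize <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  mu <- rowMeans(recording$data)
  sdev <- apply(recording$data, 1L, pop_sd)
  bad <- which(sdev <= 0)
  if (length(bad))
    stop_mibci("degenerate_channel", "constant channel(s): %s",
               paste(recording$channel_labels[bad], collapse = ", "))
  out <- (recording$data - mu) / sdev
  list(recording = eeg_recording(out, recording$fs, recording$channel_labels,
                                 recording$markers),
       params = data.frame(channel = recording$channel_labels,
                           mean = mu, sd = sdev, row.names = NULL))
}

#' Zero-phase power-line notch filter
#'
#' Second-order IIR notch (constrained biquad) at `freq_hz`, applied
#' forward-backward.  With the default quality factor of 30 a pure tone at
#' the notch frequency is suppressed by well over 20 dB while signals a few
#' Hz away pass essentially unchanged.  Pass `freq_hz = NULL` for data that
#' arrives pre-notched: the recording is returned untouched.
#'
#' @param recording an [eeg_recording()].
#' @param freq_hz interference frequency (default 60), or `NULL` to disable.
#' @param quality quality factor, center frequency over -3 dB bandwidth.
#' @return filtered [eeg_recording()].
#' @export
notch_filter <- function(recording, freq_hz = 60, quality = 30) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (is.null(freq_hz)) return(recording)
  nyq <- recording$fs / 2
  if (!is_num1(freq_hz) || freq_hz <= 0 || freq_hz >= nyq)
    stop_mibci("parameter", "freq_hz must lie in (0, fs/2)")
  w0 <- 2 * pi * freq_hz / recording$fs
  alpha <- sin(w0) / (2 * quality)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  .apply_zero_phase(recording, b, a, "notch")
}

#' Segment a recording into cue-locked epochs
#'
#' Cuts one trial per marker with the half-open sample window
#' `[round((cue_s + start) * fs), round((cue_s + end) * fs))` where `cue_s`
#' is the cue time in seconds.  Trial order follows marker order.
#'
#' @param recording a marked [eeg_recording()].
#' @param window numeric length-2 `(start, end)` in seconds relative to the
#'   cue; `start < end` (start may be negative for pre-cue baseline).
#' @return an `eeg_epochs` object: `data` (trials x channels x samples
#'   array), `labels` (factor), `fs`, `window`, `channel_labels`.
#' @export
segment_epochs <- function(recording, window = c(0.5, 3.5)) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (length(window) != 2L || window[1] >= window[2])
    stop_mibci("parameter", "window must satisfy start < end")
  mk <- recording$markers
  if (!nrow(mk)) stop_mibci("schema", "recording has no markers to segment on")
  fs <- recording$fs
  cue_s <- (mk$sample - 1L) / fs
  s0 <- round((cue_s + window[1]) * fs)        # 0-based, inclusive
  s1 <- round((cue_s + window[2]) * fs)        # 0-based, exclusive
  n_total <- ncol(recording$data)
  bad <- which(s0 < 0 | s1 > n_total)
  if (length(bad))
    stop_mibci("out_of_range",
               "epoch window exceeds recording bounds for marker(s): %s",
               paste(bad, collapse = ", "))
  lens <- s1 - s0
  if (length(unique(lens)) != 1L)
    stop_mibci("numeric", "inconsistent epoch lengths after rounding")
  n_samp <- lens[1]
  n_trial <- nrow(mk); n_ch <- nrow(recording$data)
  data <- array(0, dim = c(n_trial, n_ch, n_samp))
  for (t in seq_len(n_trial))
    data[t, , ] <- recording$data[, (s0[t] + 1L):s1[t], drop = FALSE]
  structure(list(data = data, labels = factor(mk$label), fs = fs,
                 window = as.numeric(window),
                 channel_labels = recording$channel_labels),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs))
  cat(sprintf("  window (%g, %g) s; classes: %s\n", x$window[1], x$window[2],
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Run the four preprocessing stages in order
#'
#' Band-pass, z-score normalization, notch (optional), segmentation -- the
#' fixed stage order of the pipeline.
#'
#' @param recording a marked [eeg_recording()].
#' @param config a [pipeline_config()].
#' @return an `eeg_epochs` object.
#' @export
preprocess <- function(recording, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  rec <- bandpass_filter(recording, config$band[1], config$band[2],
                         config$filter_order)
  rec <- zscore_normalize(rec)$recording
  notch <- config$notch_hz
  if (!is.null(notch) && notch >= recording$fs / 2) {
    # nothing to notch below Nyquist (e.g. 60 Hz line at fs = 100)
    notch <- NULL
  }
  rec <- notch_filter(rec, notch, config$notch_q)
  segment_epochs(rec, config$epoch_window)
}
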