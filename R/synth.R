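# Synthetic two-class motor-imagery EEG with known ground truth.
#
# Each trial superimposes band-limited mu (8-13 Hz) and beta (13-30 Hz)
# oscillations -- band-passed white noise, not pure sinusoids, so wavelet
# sub-bands receive broadband structure -- on continuous 1/f background
# noise.  On the informative channels the oscillation amplitude is scaled
# by (1 +/- effect/2) depending on the trial class, lateralized: the first
# half of the informative channels is attenuated for the first class, the
# second half for the second class (an event-related-desynchronization-like
# contrast).  Optional 60 Hz line interference can be added when the
# sampling rate allows it.

#' Synthetic recording configuration
#'
#' @param n_trials_per_class trials per class (default 100).
#' @param channel_labels channel names; default the 18-label sensorimotor
#'   grid of `"channel-set-2-bci"`.
#' @param fs sampling rate in Hz (default 100; must exceed 60 for the mu
#'   and beta bands to sit well inside Nyquist).
#' @param trial_sec trial duration in seconds (default 4; the default
#'   pipeline epoch (0.5, 3.5) s then gives 300 samples at 100 Hz).
#' @param gap_sec inter-trial gap (default 1).
#' @param informative_channels indices (into `channel_labels`) of the
#'   channels whose rhythm amplitude differs by class; default the first
#'   six (the central-row electrodes of the default grid).
#' @param effect relative mu/beta amplitude modulation between classes;
#'   0 = null (no class information), 1 = amplitudes 0.5x vs 1.5x.
#' @param noise_exponent spectral slope of the 1/f background (amplitude
#'   ~ f^(-exponent/2); default 1).
#' @param noise_amp RMS amplitude of the background (default 0.5).
#' @param osc_amp RMS amplitude of each rhythm band (default 1).
#' @param line_noise_hz line-interference frequency (e.g. 60) or `NULL`.
#' @param line_amp line-interference amplitude (default 0.5).
#' @param class_labels the two task identifiers.
#' @param seed RNG seed; the recording is fully reproducible from it.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_trials_per_class = 100L,
                         channel_labels = channel_sets()[["channel-set-2-bci"]],
                         fs = 100, trial_sec = 4, gap_sec = 1,
                         informative_channels = seq_len(min(6L, length(channel_labels))),
                         effect = 1,
                         noise_exponent = 1, noise_amp = 0.5,
                         osc_amp = 1,
                         line_noise_hz = NULL, line_amp = 0.5,
                         class_labels = c("foot", "right_hand"),
                         seed = 1L) {
  if (!is_count(n_trials_per_class)) stop_mibci("parameter", "n_trials_per_class must be >= 1")
  if (!is_num1(fs) || fs <= 60) stop_mibci("parameter", "fs must exceed 60 Hz (2 x 30 Hz)")
  if (!is_num1(effect) || effect < 0) stop_mibci("parameter", "effect must be >= 0")
  if (length(class_labels) != 2L || anyDuplicated(class_labels))
    stop_mibci("parameter", "class_labels must be two distinct strings")
  informative_channels <- as.integer(informative_channels)
  if (length(informative_channels) &&
      (min(informative_channels) < 1L ||
       max(informative_channels) > length(channel_labels)))
    stop_mibci("parameter", "informative_channels out of range")
  if (!is.null(line_noise_hz) && line_noise_hz >= fs / 2)
    stop_mibci("parameter", "line_noise_hz must be below Nyquist")
  structure(list(n_trials_per_class = as.integer(n_trials_per_class),
                 channel_labels = as.character(channel_labels),
                 fs = fs, trial_sec = trial_sec, gap_sec = gap_sec,
                 informative_channels = informative_channels,
                 effect = effect, noise_exponent = noise_exponent,
                 noise_amp = noise_amp, osc_amp = osc_amp,
                 line_noise_hz = line_noise_hz, line_amp = line_amp,
                 class_labels = sort(as.character(class_labels)),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# band-limited unit-RMS noise via FFT masking
.band_noise <- function(n, fs, low, high) {
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  freq <- (seq_len(n) - 1L) / n * fs
  freq <- pmin(freq, fs - freq)               # two-sided
  spec[freq < low | freq > high] <- 0
  y <- Re(stats::fft(spec, inverse = TRUE)) / n
  r <- sqrt(mean(y^2))
  if (r > 0) y / r else y
}

# 1/f^a background, unit RMS
.pink_noise <- function(n, fs, exponent) {
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  freq <- (seq_len(n) - 1L) / n * fs
  freq <- pmin(freq, fs - freq)
  gain <- ifelse(freq > 0, freq^(-exponent / 2), 0)
  y <- Re(stats::fft(spec * gain, inverse = TRUE)) / n
  y / sqrt(mean(y^2))
}

#' Generate a synthetic two-class motor-imagery recording
#'
#' Builds a continuous recording of interleaved trials separated by gaps,
#' with one cue marker at every trial onset; see [synth_config()] for the
#' signal model.  Identical configurations (including `seed`) give
#' identical recordings.
#'
#' @param config a [synth_config()].
#' @return a marked [eeg_recording()] with attribute
#'   `"informative_channels"` carrying the ground-truth channel labels.
#' @export
generate_recording <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs
  n_ch <- length(config$channel_labels)
  n_trial <- 2L * config$n_trials_per_class
  trial_len <- round(config$trial_sec * fs)
  gap_len <- round(config$gap_sec * fs)
  total <- gap_len + n_trial * (trial_len + gap_len)
  inf_ch <- config$informative_channels
  half <- length(inf_ch) %/% 2L
  grp1 <- inf_ch[seq_len(half)]
  grp2 <- setdiff(inf_ch, grp1)

  with_seed(config$seed, {
    classes <- sample(rep(config$class_labels, config$n_trials_per_class))
    data <- matrix(0, n_ch, total)
    for (c_i in seq_len(n_ch))
      data[c_i, ] <- config$noise_amp * .pink_noise(total, fs, config$noise_exponent)
    onsets <- gap_len + (seq_len(n_trial) - 1L) * (trial_len + gap_len) + 1L
    for (t in seq_len(n_trial)) {
      span <- onsets[t]:(onsets[t] + trial_len - 1L)
      is_first <- classes[t] == config$class_labels[1L]
      for (c_i in seq_len(n_ch)) {
        scale <- 1
        if (c_i %in% grp1) scale <- if (is_first) 1 - config$effect / 2 else 1 + config$effect / 2
        if (c_i %in% grp2) scale <- if (is_first) 1 + config$effect / 2 else 1 - config$effect / 2
        osc <- config$osc_amp * (.band_noise(trial_len, fs, 8, 13) +
                                 .band_noise(trial_len, fs, 13, 30))
        data[c_i, span] <- data[c_i, span] + scale * osc
      }
    }
    if (!is.null(config$line_noise_hz)) {
      tt <- (seq_len(total) - 1L) / fs
      line <- config$line_amp * sin(2 * pi * config$line_noise_hz * tt)
      data <- sweep(data, 2L, line, "+")
    }
    rec <- eeg_recording(data, fs, config$channel_labels,
                         markers = data.frame(sample = onsets, label = classes,
                                              stringsAsFactors = FALSE))
    attr(rec, "informative_channels") <- config$channel_labels[inf_ch]
    rec
  })
}

#' Named fixture suite for end-to-end testing
#'
#' Four study fixtures with known expected behavior: a null-effect
#' recording (chance-level decodable), strong-effect recordings over the
#' 18- and 13-channel registry sets (highly decodable), and a 60 Hz
#' line-noise-contaminated recording at 250 Hz for notch verification.
#'
#' @param seed base RNG seed.
#' @param n_trials_per_class trials per class for each fixture.
#' @return named list; each element has `recording`, `config`, and
#'   `expected` (a descriptive list of the properties the fixture was
#'   built to exhibit).
#' @export
make_fixture_suite <- function(seed = 1L, n_trials_per_class = 100L) {
  ch18 <- channel_sets()[["channel-set-2-bci"]]
  ch13 <- channel_sets()[["channel-set-1-auto"]]
  cfgs <- list(
    "null-effect" = synth_config(n_trials_per_class, ch18, effect = 0,
                                 seed = seed),
    "strong-effect-18-channel" = synth_config(n_trials_per_class, ch18,
                                              effect = 1, seed = seed + 1L),
    "strong-effect-13-channel" = synth_config(n_trials_per_class, ch13,
                                              informative_channels = 1:6,
                                              effect = 1, seed = seed + 2L),
    "line-noise-contaminated" = synth_config(n_trials_per_class, ch18,
                                             fs = 250, effect = 1,
                                             line_noise_hz = 60,
                                             seed = seed + 3L))
  expected <- list(
    "null-effect" = list(cv_accuracy = "within the binomial 95% interval of 0.5"),
    "strong-effect-18-channel" = list(cv_accuracy = ">= 0.90 with linear SVM",
                                      n_channels = 18L, fused_width = 1836L),
    "strong-effect-13-channel" = list(n_channels = 13L, fused_width = 1326L),
    "line-noise-contaminated" = list(post_notch_60hz = ">= 20 dB reduction"))
  out <- lapply(names(cfgs), function(nm)
    list(recording = generate_recording(cfgs[[nm]]), config = cfgs[[nm]],
         expected = expected[[nm]]))
  names(out) <- names(cfgs)
  out
}
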