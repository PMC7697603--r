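# Feature set 1: six per-channel time-domain statistics of each epoch --
# RMS, quadratic Renyi entropy of the sample-energy distribution, Hjorth
# mobility and complexity, waveform length, and mean absolute value.

.time_stat_order <- c("rms", "renyi", "mobility", "complexity", "wl", "mav")

#' Root mean square of a signal
#' @param y numeric vector.
#' @return `sqrt(mean(y^2))`.
#' @export
rms <- function(y) {
  if (!length(y)) stop_mibci("empty_input", "rms of an empty vector")
  sqrt(mean(y^2))
}

#' Renyi entropy of a signal's energy distribution
#'
#' The samples are mapped to the normalized energy distribution
#' `p_j = y_j^2 / sum(y^2)` and the order-`q` Renyi entropy
#' `log(sum(p^q)) / (1 - q)` (natural log) is returned.  It is 0 when all
#' energy sits in one sample and `log(M)` when energy is spread uniformly.
#'
#' @param y numeric vector, not all zeros.
#' @param q entropy order, `q > 0`, `q != 1` (the Shannon limit is not
#'   implemented); default 2.
#' @return entropy in nats, in `[0, log(length(y))]`.
#' @export
renyi_entropy <- function(y, q = 2) {
  if (!is_num1(q) || q <= 0 || q == 1)
    stop_mibci("parameter", "q must be > 0 and != 1")
  e <- sum(y^2)
  if (e <= 0) stop_mibci("degenerate_distribution", "all-zero signal has no energy distribution")
  p <- y^2 / e
  p <- p[p > 0]
  log(sum(p^q)) / (1 - q)
}

#' Hjorth mobility
#'
#' `sqrt(var(diff(y)) / var(y))` with population variances; the derivative
#' is the first difference (an fs-independent convention: any sampling-rate
#' scaling is a constant shared by every trial and cancels in complexity).
#'
#' @param y numeric vector, at least 3 samples.
#' @return mobility (> 0).
#' @export
hjorth_mobility <- function(y) {
  if (length(y) < 3L) stop_mibci("empty_input", "mobility needs at least 3 samples")
  v0 <- mean((y - mean(y))^2)
  d <- diff(y)
  v1 <- mean((d - mean(d))^2)
  if (v0 <= 0 || v1 <= 0)
    stop_mibci("degenerate_signal", "zero variance in signal or first difference")
  sqrt(v1 / v0)
}

#' Hjorth complexity
#'
#' Ratio of the mobility of the first difference to the mobility of the
#' signal.
#'
#' @param y numeric vector, at least 4 samples.
#' @return complexity (> 0).
#' @export
hjorth_complexity <- function(y) {
  if (length(y) < 4L) stop_mibci("empty_input", "complexity needs at least 4 samples")
  hjorth_mobility(diff(y)) / hjorth_mobility(y)
}

#' Waveform length
#'
#' Total variation of the signal: `sum(abs(diff(y)))`.
#'
#' @param y numeric vector, at least 2 samples.
#' @return waveform length (>= 0).
#' @export
waveform_length <- function(y) {
  if (length(y) < 2L) stop_mibci("empty_difference", "waveform length needs >= 2 samples")
  sum(abs(diff(y)))
}

#' Mean absolute value
#' @param y numeric vector.
#' @return `mean(abs(y))`.
#' @export
mean_abs_value <- function(y) {
  if (!length(y)) stop_mibci("empty_input", "mean absolute value of an empty vector")
  mean(abs(y))
}

#' Hjorth activity (variance)
#'
#' Population variance of the signal.  Not part of the default six-feature
#' layout; used by the `adjacent-gamma-plus-activity` layout variant.
#'
#' @param y numeric vector.
#' @return variance (>= 0).
#' @export
hjorth_activity <- function(y) {
  if (!length(y)) stop_mibci("empty_input", "activity of an empty vector")
  mean((y - mean(y))^2)
}

.feat_name <- function(channel, domain, subband, stat)
  sprintf("CH:%s|%s|%s|%s", channel, domain, subband, stat)

#' Extract the time-domain feature block
#'
#' Computes the six time-domain features for every trial and channel of an
#' epoch set.  Columns are channel-major in the order of the channel set,
#' with statistics ordered rms, renyi, mobility, complexity, wl, mav, and
#' named `CH:<label>|time|NA|<stat>`.
#'
#' @param epochs an `eeg_epochs` object from [segment_epochs()].
#' @param channel_set a `channel_set`, registry name, label vector, or
#'   `NULL` for all channels.
#' @param renyi_q Renyi entropy order (default 2).
#' @param include_activity if `TRUE`, append a seventh `activity` column per
#'   channel (off by default).
#' @return numeric matrix, trials x (6 * channels), with canonical column
#'   names.
#' @export
extract_time_features <- function(epochs, channel_set = NULL, renyi_q = 2,
                                  include_activity = FALSE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  ch_labels <- .resolve_epoch_channels(epochs, channel_set)
  ch_idx <- match(ch_labels, epochs$channel_labels)
  stats <- c(.time_stat_order, if (include_activity) "activity")
  n_trial <- dim(epochs$data)[1]
  out <- matrix(NA_real_, n_trial, length(ch_labels) * length(stats))
  colnames(out) <- as.vector(vapply(ch_labels, function(ch)
    .feat_name(ch, "time", "NA", stats), character(length(stats))))
  col <- 0L
  for (ci in seq_along(ch_idx)) {
    M <- epochs$data[, ch_idx[ci], , drop = TRUE]
    if (is.null(dim(M))) M <- matrix(M, nrow = n_trial)
    for (st in stats) {
      col <- col + 1L
      fun <- switch(st,
                    rms = rms,
                    renyi = function(y) renyi_entropy(y, renyi_q),
                    mobility = hjorth_mobility,
                    complexity = hjorth_complexity,
                    wl = waveform_length,
                    mav = mean_abs_value,
                    activity = hjorth_activity)
      vals <- try(apply(M, 1L, fun), silent = TRUE)
      if (inherits(vals, "try-error"))
        stop_mibci("degenerate_signal",
                   "feature '%s' failed on channel %s: %s", st, ch_labels[ci],
                   attr(vals, "condition")$message)
      out[, col] <- vals
    }
  }
  out
}

# map a channel-set argument to epoch channel labels
.resolve_epoch_channels <- function(epochs, channel_set) {
  if (is.null(channel_set)) return(epochs$channel_labels)
  if (inherits(channel_set, "channel_set")) {
    labels <- channel_set$labels
  } else if (length(channel_set) == 1L && channel_set %in% names(.channel_registry)) {
    labels <- .channel_registry[[channel_set]]
  } else {
    labels <- as.character(channel_set)
  }
  missing <- setdiff(labels, epochs$channel_labels)
  if (length(missing))
    stop_mibci("channel_not_found", "channel(s) not present in epochs: %s",
               paste(missing, collapse = ", "))
  labels
}
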