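#' Pipeline configuration
#'
#' Collects every tunable stage parameter of the motor-imagery pipeline in
#' one validated object.  Defaults follow the study conditions the package
#' implements: a 10-30 Hz 5th-order Butterworth band-pass (covering the
#' upper mu and beta rhythms), a 60 Hz notch (disable with
#' `notch_hz = NULL` for pre-notched data), cue-locked epochs at
#' (0.5, 3.5) s, a 4-level db4 wavelet packet bank, quadratic Renyi
#' entropy, and a linear SVM under stratified 10-fold cross-validation.
#'
#' @param band numeric length-2, band-pass edges in Hz (low < high).
#' @param filter_order Butterworth order (>= 1).
#' @param notch_hz power-line frequency to notch, or `NULL` to disable.
#' @param notch_q notch quality factor (center frequency / -3 dB width).
#' @param epoch_window numeric length-2, epoch start/end in seconds
#'   relative to the cue (start < end).
#' @param wavelet orthogonal wavelet family, e.g. `"db4"` (see
#'   [wavelet_filter()]).
#' @param wpd_level wavelet packet decomposition depth (>= 1).
#' @param renyi_q Renyi entropy order (> 0, != 1).
#' @param classifier one of `"svm-linear"`, `"lda"`, `"knn"`.
#' @param knn_k odd neighbor count for k-NN.
#' @param svm_cost linear SVM regularization constant.
#' @param cv_folds number of cross-validation folds (>= 2).
#' @param seed integer RNG seed controlling fold assignment and any
#'   stochastic stage.
#' @param channel_set registry name or explicit label vector (resolved
#'   against the recording at run time); `NULL` means all channels.
#' @param wpd_layout `"cyclic-gamma"` (default; six statistics on every
#'   terminal node, adjacent-band ratio closed cyclically) or
#'   `"adjacent-gamma-plus-activity"` (one ratio per interior adjacency plus
#'   the Hjorth activity time feature; same total width).
#' @return object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(band = c(10, 30),
                            filter_order = 5L,
                            notch_hz = 60,
                            notch_q = 30,
                            epoch_window = c(0.5, 3.5),
                            wavelet = "db4",
                            wpd_level = 4L,
                            renyi_q = 2,
                            classifier = c("svm-linear", "lda", "knn"),
                            knn_k = 5L,
                            svm_cost = 1,
                            cv_folds = 10L,
                            seed = 1L,
                            channel_set = NULL,
                            wpd_layout = c("cyclic-gamma",
                                           "adjacent-gamma-plus-activity")) {
  classifier <- match.arg(classifier)
  wpd_layout <- match.arg(wpd_layout)
  if (length(band) != 2L || !all(is.finite(band)) || band[1] <= 0 || band[1] >= band[2])
    stop_mibci("parameter", "band must satisfy 0 < low < high")
  if (!is_count(filter_order)) stop_mibci("parameter", "filter_order must be a positive integer")
  if (!is.null(notch_hz) && (!is_num1(notch_hz) || notch_hz <= 0))
    stop_mibci("parameter", "notch_hz must be positive or NULL")
  if (length(epoch_window) != 2L || epoch_window[1] >= epoch_window[2])
    stop_mibci("parameter", "epoch_window must satisfy start < end")
  if (!is_count(wpd_level)) stop_mibci("parameter", "wpd_level must be >= 1")
  if (!is_num1(renyi_q) || renyi_q <= 0 || renyi_q == 1)
    stop_mibci("parameter", "renyi_q must be > 0 and != 1")
  if (!is_count(knn_k) || knn_k %% 2L == 0L)
    stop_mibci("parameter", "knn_k must be an odd positive integer")
  if (!is_count(cv_folds, min = 2L)) stop_mibci("parameter", "cv_folds must be >= 2")
  if (!is_count(seed, min = 0L)) stop_mibci("parameter", "seed must be a non-negative integer")
  structure(list(band = as.numeric(band), filter_order = as.integer(filter_order),
                 notch_hz = notch_hz, notch_q = notch_q,
                 epoch_window = as.numeric(epoch_window),
                 wavelet = wavelet, wpd_level = as.integer(wpd_level),
                 renyi_q = renyi_q, classifier = classifier,
                 knn_k = as.integer(knn_k), svm_cost = svm_cost,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 channel_set = channel_set, wpd_layout = wpd_layout),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  band: %g-%g Hz (Butterworth order %d, zero-phase)\n",
              x$band[1], x$band[2], x$filter_order))
  cat(sprintf("  notch: %s\n",
              if (is.null(x$notch_hz)) "disabled"
              else sprintf("%g Hz (Q = %g)", x$notch_hz, x$notch_q)))
  cat(sprintf("  epoch window: (%g, %g) s relative to cue\n",
              x$epoch_window[1], x$epoch_window[2]))
  cat(sprintf("  WPD: %s, level %d, layout %s; Renyi q = %g\n",
              x$wavelet, x$wpd_level, x$wpd_layout, x$renyi_q))
  cat(sprintf("  classifier: %s (k = %d, C = %g), %d-fold CV, seed %d\n",
              x$classifier, x$knn_k, x$svm_cost, x$cv_folds, x$seed))
  cat(sprintf("  channel set: %s\n",
              if (is.null(x$channel_set)) "all channels"
              else paste(x$channel_set, collapse = ", ")))
  invisible(x)
}
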