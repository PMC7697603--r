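#' Construct a raw EEG recording
#'
#' An `eeg_recording` holds a continuous multichannel EEG signal (one row per
#' channel, in microvolts or normalized units), its sampling rate, 10-20
#' system channel labels, and cue markers.  Markers carry the sample index of
#' each task cue (1-based) together with a class label; at most two distinct
#' class labels may occur, since the pipeline is a two-class motor-imagery
#' classifier.
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector of unique channel names, one per
#'   row of `data`.
#' @param markers data frame with columns `sample` (integer cue onset,
#'   1-based, within `[1, ncol(data)]`) and `label` (task identifier);
#'   `NULL` for an unmarked recording.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels, markers = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop_mibci("schema", "data must be a numeric channels x samples matrix")
  if (!is_num1(fs) || fs <= 0)
    stop_mibci("parameter", "fs must be a single positive number")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    stop_mibci("schema", "number of channel labels (%d) != number of data rows (%d)",
               length(channel_labels), nrow(data))
  if (anyDuplicated(channel_labels))
    stop_mibci("schema", "channel labels must be unique")
  if (is.null(markers)) {
    markers <- data.frame(sample = integer(0), label = character(0),
                          stringsAsFactors = FALSE)
  } else {
    markers <- as.data.frame(markers, stringsAsFactors = FALSE)
    if (!all(c("sample", "label") %in% names(markers)))
      stop_mibci("schema", "markers must have columns 'sample' and 'label'")
    markers$sample <- as.integer(markers$sample)
    markers$label <- as.character(markers$label)
    if (nrow(markers)) {
      if (any(markers$sample < 1L) || any(markers$sample > ncol(data)))
        stop_mibci("schema", "marker sample indices must lie within [1, %d]", ncol(data))
      nclass <- length(unique(markers$label))
      if (nclass > 2L)
        stop_mibci("unsupported_task",
                   "recording carries %d distinct class labels; only two-class tasks are supported",
                   nclass)
    }
  }
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 markers = markers),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(utils::head(x$channel_labels, 8), collapse = ", "),
      if (length(x$channel_labels) > 8) "..." else "", "\n")
  if (nrow(x$markers)) {
    tab <- table(x$markers$label)
    cat(sprintf("  markers: %d (%s)\n", nrow(x$markers),
                paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  } else cat("  markers: none\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' The two task class labels of a marked recording
#'
#' Returns the sorted pair of distinct marker labels.  By convention the
#' lexicographically larger label is treated as the positive class throughout
#' the evaluation module (overridable there).
#'
#' @param recording an `eeg_recording`.
#' @return character vector of the distinct labels, sorted.
#' @export
task_labels <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  sort(unique(recording$markers$label))
}
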