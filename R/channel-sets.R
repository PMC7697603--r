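# Named sensorimotor channel-set registry.
#
# The shipped sets are electrode subsets over the sensorimotor cortex that
# are commonly used for two-class motor imagery instead of a full montage:
# a minimal C3/Cz/C4 triple, an 18-electrode grid around the central sulcus,
# and a 13-electrode set built from the deduplicated 10-20 neighborhoods of
# C3 (FC3, C5, CP3, C1), Cz (FCz, C1, CPz, C2) and C4 (FC4, C2, CP4, C6).

.channel_registry <- list(
  "channel-set-1-bci"  = c("C3", "Cz", "C4"),
  "channel-set-2-bci"  = c("C5", "C3", "C1", "C2", "C4", "C6",
                           "CP5", "CP3", "CP1", "CP2", "CP4", "CP6",
                           "P5", "P3", "P1", "P2", "P4", "P6"),
  "channel-set-1-auto" = c("C3", "FC3", "C5", "CP3", "C1",
                           "Cz", "FCz", "CPz",
                           "C2", "C4", "FC4", "CP4", "C6"),
  "channel-set-2-auto" = c("C3", "Cz", "C4")
)

#' List the registered channel sets
#'
#' @return named list of character vectors of 10-20 channel labels.
#' @export
channel_sets <- function() .channel_registry

#' Resolve a channel set against a recording
#'
#' Accepts either the name of a registered set (see [channel_sets()]) or an
#' explicit character vector of labels, and checks that every label is
#' present in the recording.
#'
#' @param name_or_labels registry name (length-1 character) or explicit label
#'   vector (length > 1, or any vector not matching a registry name).
#' @param recording an [eeg_recording()] whose labels the set must resolve
#'   against.
#' @return object of class `channel_set`: list with `name` and `labels`.
#' @export
resolve_channel_set <- function(name_or_labels, recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (length(name_or_labels) == 1L && name_or_labels %in% names(.channel_registry)) {
    name <- name_or_labels
    labels <- .channel_registry[[name]]
  } else if (length(name_or_labels) == 1L && !name_or_labels %in% recording$channel_labels) {
    stop_mibci("registry", "unknown channel set '%s' (registered: %s)",
               name_or_labels, paste(names(.channel_registry), collapse = ", "))
  } else {
    name <- "custom"
    labels <- as.character(name_or_labels)
    if (anyDuplicated(labels))
      stop_mibci("schema", "channel set labels must be unique")
  }
  missing <- setdiff(labels, recording$channel_labels)
  if (length(missing))
    stop_mibci("channel_not_found", "channel(s) not present in recording: %s",
               paste(missing, collapse = ", "))
  structure(list(name = name, labels = labels), class = "channel_set")
}

#' @export
print.channel_set <- function(x, ...) {
  cat(sprintf("<channel_set> %s (%d): %s\n", x$name, length(x$labels),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}
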