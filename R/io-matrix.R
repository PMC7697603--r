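# Delimited matrix-bundle dialect: a plain numeric text matrix (one channel
# per row, comma or tab separated) plus a YAML sidecar holding the sampling
# rate, channel labels and cue markers.  Lossless and diff-friendly, which
# makes it the preferred fixture format.

#' Read a matrix-bundle recording
#'
#' @param matrix_path delimited numeric matrix, rows = channels.
#' @param sidecar_path YAML sidecar with fields `fs`, `labels` and optional
#'   `markers` (list of `{sample, label}` with 1-based sample indices).
#' @return an [eeg_recording()].
#' @export
read_matrix_bundle <- function(matrix_path, sidecar_path) {
  if (!file.exists(matrix_path)) stop_mibci("format", "no such file: %s", matrix_path)
  if (!file.exists(sidecar_path)) stop_mibci("format", "no such file: %s", sidecar_path)
  first <- readLines(matrix_path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  mat <- as.matrix(utils::read.table(matrix_path, sep = sep, header = FALSE,
                                     colClasses = "numeric"))
  dimnames(mat) <- NULL
  side <- yaml::read_yaml(sidecar_path)
  if (is.null(side$fs) || is.null(side$labels))
    stop_mibci("schema", "sidecar must define 'fs' and 'labels'")
  labels <- unlist(side$labels)
  if (length(labels) != nrow(mat))
    stop_mibci("schema", "sidecar lists %d labels but matrix has %d rows",
               length(labels), nrow(mat))
  markers <- NULL
  if (length(side$markers)) {
    markers <- data.frame(
      sample = vapply(side$markers, function(m) as.integer(m$sample), integer(1)),
      label  = vapply(side$markers, function(m) as.character(m$label), character(1)),
      stringsAsFactors = FALSE)
  }
  eeg_recording(mat, fs = as.numeric(side$fs), channel_labels = labels,
                markers = markers)
}

#' Write a matrix-bundle recording
#'
#' Inverse of [read_matrix_bundle()]; the round trip is bit-identical up to
#' the decimal printing precision (17 significant digits, i.e. exact for
#' doubles).
#'
#' @param recording an [eeg_recording()].
#' @param matrix_path,sidecar_path output paths.
#' @param sep field separator, `","` or `"\t"`.
#' @return invisibly, the two paths.
#' @export
write_matrix_bundle <- function(recording, matrix_path, sidecar_path, sep = ",") {
  stopifnot(inherits(recording, "eeg_recording"))
  lines <- apply(recording$data, 1L, function(row)
    paste(sprintf("%.17g", row), collapse = sep))
  writeLines(lines, matrix_path)
  side <- list(fs = recording$fs, labels = as.list(recording$channel_labels))
  if (nrow(recording$markers))
    side$markers <- lapply(seq_len(nrow(recording$markers)), function(i)
      list(sample = recording$markers$sample[i],
           label = recording$markers$label[i]))
  yaml::write_yaml(side, sidecar_path)
  invisible(c(matrix_path, sidecar_path))
}

#' Write a feature matrix as delimited text
#'
#' Tab-separated, one trial per row, with a leading `class` column and the
#' canonical feature-name header `CH:<label>|<domain>|<subband-or-NA>|<stat>`.
#'
#' @param features an [mi_features()] object.
#' @param path output path.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "mi_features"))
  df <- data.frame(class = as.character(features$labels),
                   features$X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#'
#' @param path input path.
#' @return an [mi_features()] object.
#' @export
read_features <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"class" %in% names(df)) stop_mibci("schema", "feature table lacks a 'class' column")
  X <- as.matrix(df[, setdiff(names(df), "class"), drop = FALSE])
  mi_features(X, labels = df$class)
}
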