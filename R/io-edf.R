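# Minimal EDF/EDF+ support: 16-bit European Data Format with an optional
# "EDF Annotations" signal carrying cue markers as time-stamped annotation
# lists (TALs).  Covers what the pipeline needs -- equal sampling rate across
# data channels, annotations mapped to two-class cue markers -- and is
# deliberately not a general-purpose EDF implementation.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)
}

.edf_num <- function(x, width = 8L) {
  s <- formatC(x, format = "g", digits = 7)
  while (nchar(s) > width) {
    s <- formatC(x, format = "g", digits = max(1L, nchar(s) - width + 5L))
    x <- as.numeric(s)
  }
  .edf_pad(s, width)
}

#' Write a recording as EDF/EDF+
#'
#' Signals are quantized to 16 bits over each channel's physical range, so
#' the round trip through [read_edf()] is exact to about
#' `range/2^15` per channel.  Markers, if present, are stored in an EDF+
#' annotations signal (one TAL per cue, onset in seconds).
#'
#' @param recording an [eeg_recording()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  data <- recording$data
  n_ch <- nrow(data); n_samp <- ncol(data)
  has_ann <- nrow(recording$markers) > 0L
  ns <- n_ch + as.integer(has_ann)
  duration <- n_samp / recording$fs

  pmin <- apply(data, 1L, min); pmax <- apply(data, 1L, max)
  flat <- pmax - pmin <= 0
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  ann_raw <- raw(0)
  if (has_ann) {
    tal <- function(onset, text)
      c(charToRaw(sprintf("+%s", formatC(onset, format = "f", digits = 6))),
        as.raw(0x14), charToRaw(text), as.raw(0x14), as.raw(0x00))
    ann_raw <- c(tal(0, ""),  # record-start timestamp TAL
                 unlist(lapply(seq_len(nrow(recording$markers)), function(i)
                   tal((recording$markers$sample[i] - 1L) / recording$fs,
                       recording$markers$label[i]))))
    if (length(ann_raw) %% 2L) ann_raw <- c(ann_raw, as.raw(0x00))
  }
  ann_nsamp <- length(ann_raw) / 2L

  con <- file(path, "wb"); on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  # fixed header, 256 bytes
  wr(.edf_pad("0", 8))
  wr(.edf_pad("X X X X", 80))
  wr(.edf_pad("Startdate 01-JAN-2000 X X mibci", 80))
  wr(.edf_pad("01.01.00", 8)); wr(.edf_pad("00.00.00", 8))
  wr(.edf_pad(256L * (ns + 1L), 8))
  wr(.edf_pad(if (has_ann) "EDF+C" else "", 44))
  wr(.edf_pad(1L, 8))               # single data record
  wr(.edf_num(duration, 8))
  wr(.edf_pad(ns, 4))
  # signal headers
  labels <- c(recording$channel_labels, if (has_ann) "EDF Annotations")
  for (l in labels) wr(.edf_pad(l, 16))
  for (i in seq_len(ns)) wr(.edf_pad("", 80))                 # transducer
  for (i in seq_len(ns)) wr(.edf_pad(if (i <= n_ch) "uV" else "", 8))
  for (i in seq_len(ns)) wr(if (i <= n_ch) .edf_num(pmin[i]) else .edf_num(-1))
  for (i in seq_len(ns)) wr(if (i <= n_ch) .edf_num(pmax[i]) else .edf_num(1))
  for (i in seq_len(ns)) wr(.edf_pad(dmin, 8))
  for (i in seq_len(ns)) wr(.edf_pad(dmax, 8))
  for (i in seq_len(ns)) wr(.edf_pad("", 80))                 # prefiltering
  for (i in seq_len(ns)) wr(.edf_pad(if (i <= n_ch) n_samp else ann_nsamp, 8))
  for (i in seq_len(ns)) wr(.edf_pad("", 32))
  # one data record: all samples per signal, int16 little-endian
  for (i in seq_len(n_ch)) {
    dig <- round((data[i, ] - pmin[i]) / (pmax[i] - pmin[i]) * (dmax - dmin) + dmin)
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  if (has_ann) writeBin(ann_raw, con)
  invisible(path)
}

.edf_parse_tals <- function(bytes) {
  chunks <- split(bytes, cumsum(bytes == as.raw(0)))
  out <- list()
  for (ch in chunks) {
    ch <- ch[ch != as.raw(0)]
    if (!length(ch)) next
    txt <- rawToChar(ch)
    # onset \x15 duration? \x14 annotation \x14
    m <- regmatches(txt, regexec("^([+-][0-9.]+)(\x15[0-9.]+)?\x14(.*)\x14", txt))[[1]]
    if (length(m) == 4L && nzchar(m[4]))
      out[[length(out) + 1L]] <- list(onset = as.numeric(m[2]), label = m[4])
  }
  out
}

#' Read an EDF/EDF+ recording
#'
#' All ordinary signals must share one sampling rate; an `EDF Annotations`
#' signal, if present, is parsed and its annotations become cue markers.
#' When `task_labels` is given only matching annotations are kept, which is
#' the way to read files whose annotation stream mixes cues with other
#' events.
#'
#' @param path EDF file.
#' @param task_labels optional character vector of the (at most two) task
#'   names to keep as markers.
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path, task_labels = NULL) {
  if (!file.exists(path)) stop_mibci("format", "no such file: %s", path)
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    if (length(s) == 0L || nchar(s, type = "bytes") < n)
      stop_mibci("format", "truncated EDF header in %s", path)
    trimws(s)
  }
  rd(8)                                    # version
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  rd(44)                                   # reserved / EDF+ flag
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (!is.finite(ns) || ns < 1L) stop_mibci("format", "unparseable EDF header in %s", path)
  sig_field <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- sig_field(16)
  sig_field(80)
  sig_field(8)                             # physical dimension
  pmin <- as.numeric(sig_field(8)); pmax <- as.numeric(sig_field(8))
  dmin <- as.numeric(sig_field(8)); dmax <- as.numeric(sig_field(8))
  sig_field(80)
  nsamp <- as.integer(sig_field(8))
  sig_field(32)

  is_ann <- labels == "EDF Annotations"
  data_idx <- which(!is_ann)
  if (!length(data_idx)) stop_mibci("format", "EDF file has no data signals")
  if (length(unique(nsamp[data_idx])) != 1L)
    stop_mibci("unsupported_dialect",
               "EDF signals have differing sampling rates; not supported")
  fs <- nsamp[data_idx[1]] / rec_dur

  chans <- vector("list", length(data_idx)); names(chans) <- labels[data_idx]
  for (i in seq_along(chans)) chans[[i]] <- numeric(0)
  ann_bytes <- raw(0)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      if (is_ann[s]) {
        ann_bytes <- c(ann_bytes, readBin(con, "raw", n = 2L * nsamp[s]))
      } else {
        dig <- readBin(con, "integer", n = nsamp[s], size = 2L,
                       signed = TRUE, endian = "little")
        if (length(dig) < nsamp[s]) stop_mibci("format", "truncated EDF data in %s", path)
        j <- match(s, data_idx)
        phys <- (dig - dmin[s]) / (dmax[s] - dmin[s]) * (pmax[s] - pmin[s]) + pmin[s]
        chans[[j]] <- c(chans[[j]], phys)
      }
    }
  }
  data <- do.call(rbind, chans)

  markers <- NULL
  if (any(is_ann)) {
    tals <- .edf_parse_tals(ann_bytes)
    if (length(tals)) {
      markers <- data.frame(
        sample = vapply(tals, function(t) as.integer(round(t$onset * fs)) + 1L, integer(1)),
        label  = vapply(tals, function(t) t$label, character(1)),
        stringsAsFactors = FALSE)
      if (!is.null(task_labels))
        markers <- markers[markers$label %in% task_labels, , drop = FALSE]
      if (!nrow(markers)) markers <- NULL
    }
  }
  if (is.null(markers)) warning("EDF file carries no task annotations; markers empty")
  eeg_recording(data, fs = fs, channel_labels = labels[data_idx], markers = markers)
}
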