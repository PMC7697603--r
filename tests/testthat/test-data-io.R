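test_that("recording construction enforces the container invariants", {
  data <- matrix(rnorm(300), 3, 100)
  rec <- eeg_recording(data, 100, c("C3", "Cz", "C4"),
                       markers = data.frame(sample = c(10L, 60L),
                                            label = c("a", "b")))
  expect_identical(dim(rec), c(3L, 100L))
  expect_identical(task_labels(rec), c("a", "b"))

  expect_error(eeg_recording(data, 100, c("C3", "Cz")), "labels")
  expect_error(eeg_recording(data, 100, c("C3", "C3", "C4")), "unique")
  expect_error(eeg_recording(data, 100, c("C3", "Cz", "C4"),
                             markers = data.frame(sample = 101L, label = "a")),
               "within")
  expect_error(eeg_recording(data, 100, c("C3", "Cz", "C4"),
                             markers = data.frame(sample = c(1L, 2L, 3L),
                                                  label = c("a", "b", "c"))),
               class = "mibci_unsupported_task")
})

test_that("matrix bundle round trip is lossless", {
  rec <- test_recording(markers = test_markers(4, 200, offset = 5L))
  mp <- tempfile(fileext = ".csv"); sp <- tempfile(fileext = ".yaml")
  write_matrix_bundle(rec, mp, sp)
  back <- read_matrix_bundle(mp, sp)
  expect_equal(back$data, rec$data, ignore_attr = TRUE)
  expect_identical(back$fs, rec$fs)
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_identical(back$markers, rec$markers)

  # tab-separated dialect too
  write_matrix_bundle(rec, mp, sp, sep = "\t")
  expect_equal(read_matrix_bundle(mp, sp)$data, rec$data, ignore_attr = TRUE)
})

test_that("matrix bundle readers reject malformed sidecars", {
  rec <- test_recording()
  mp <- tempfile(); sp <- tempfile()
  write_matrix_bundle(rec, mp, sp)
  side <- yaml::read_yaml(sp)
  side$labels <- side$labels[1:2]
  yaml::write_yaml(side, sp)
  expect_error(read_matrix_bundle(mp, sp), class = "mibci_schema")

  write_matrix_bundle(rec, mp, sp)
  side <- yaml::read_yaml(sp)
  side$markers <- list(list(sample = 1, label = "x"),
                       list(sample = 2, label = "y"),
                       list(sample = 3, label = "z"))
  yaml::write_yaml(side, sp)
  expect_error(read_matrix_bundle(mp, sp), class = "mibci_unsupported_task")
})

test_that("EDF round trip preserves data within 16-bit quantization", {
  rec <- test_recording(n_ch = 3L, n_samp = 500L,
                        markers = test_markers(3, 150, offset = 10L))
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_equal(back$fs, rec$fs)
  tol <- (max(rec$data) - min(rec$data)) / 2^15
  expect_lt(max(abs(back$data - rec$data)), tol)
  expect_identical(back$markers$sample, rec$markers$sample)
  expect_identical(back$markers$label, rec$markers$label)
})

test_that("EDF without annotations reads back with empty markers and a warning", {
  rec <- test_recording(n_samp = 200L)
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  expect_warning(back <- read_edf(path), "annotation")
  expect_identical(nrow(back$markers), 0L)
})

test_that("EDF task-label filter keeps only the configured cues", {
  path <- tempfile(fileext = ".edf")
  rec <- eeg_recording(matrix(rnorm(200), 2, 100), 50, c("C3", "C4"),
                       markers = data.frame(sample = c(10L, 50L, 90L),
                                            label = c("foot", "rest", "foot")))
  write_edf(rec, path)
  filtered <- read_edf(path, task_labels = "foot")
  expect_identical(filtered$markers$label, c("foot", "foot"))
  expect_identical(filtered$markers$sample, c(10L, 90L))
})

test_that("channel-set registry ships the four named sets with fixed sizes", {
  reg <- channel_sets()
  expect_identical(lengths(reg[c("channel-set-1-bci", "channel-set-2-bci",
                                 "channel-set-2-auto", "channel-set-1-auto")]),
                   c("channel-set-1-bci" = 3L, "channel-set-2-bci" = 18L,
                     "channel-set-2-auto" = 3L, "channel-set-1-auto" = 13L))
  expect_identical(reg[["channel-set-2-bci"]][1:3], c("C5", "C3", "C1"))
  expect_identical(reg[["channel-set-1-bci"]], c("C3", "Cz", "C4"))
  # the 13-label set is the deduplicated union of the three neighborhoods
  expect_true(all(c("C3", "FC3", "C5", "CP3", "C1", "Cz", "FCz", "CPz",
                    "C2", "C4", "FC4", "CP4", "C6") %in%
                    reg[["channel-set-1-auto"]]))
  expect_false(anyDuplicated(reg[["channel-set-1-auto"]]) > 0)
})

test_that("channel sets resolve against recordings with clear errors", {
  rec <- generate_recording(synth_config(2L, seed = 1L))
  cs <- resolve_channel_set("channel-set-2-bci", rec)
  expect_length(cs$labels, 18L)
  cs2 <- resolve_channel_set(c("C3", "C4"), rec)
  expect_identical(cs2$labels, c("C3", "C4"))
  expect_error(resolve_channel_set("no-such-set", rec), class = "mibci_registry")
  err <- tryCatch(resolve_channel_set(c("C3", "XX9"), rec), error = identity)
  expect_s3_class(err, "mibci_channel_not_found")
  expect_match(conditionMessage(err), "XX9")
})

test_that("feature tables round trip through delimited text", {
  X <- matrix(rnorm(20), 5, 4,
              dimnames = list(NULL, c("CH:C3|time|NA|rms", "CH:C3|time|NA|mav",
                                      "CH:C4|wpd|b01|mu", "CH:C4|wpd|b01|pav")))
  fm <- mi_features(X, rep(c("foot", "right_hand"), length.out = 5))
  path <- tempfile(fileext = ".tsv")
  write_features(fm, path)
  back <- read_features(path)
  expect_identical(colnames(back$X), colnames(X))
  expect_equal(back$X, X, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(as.character(back$labels), as.character(fm$labels))
})
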