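# End-to-end experiment driver: preprocess -> feature extraction ->
# (optional, fold-nested) hybrid feature selection -> cross-validated
# evaluation, with per-stage bookkeeping.
#
# The four experiment kinds correspond to the feature configurations a
# two-class MI study compares: time-domain features only, wavelet packet
# features only, their fusion, and fusion plus hybrid feature selection.

#' Run one experiment end to end
#'
#' @param recording a marked [eeg_recording()].
#' @param experiment `"time-only"`, `"wpd-only"`, `"hybrid"`, or
#'   `"hybrid+fs"`.
#' @param config a [pipeline_config()]; its `channel_set`, filters, epoch
#'   window, wavelet bank, classifier and CV settings drive every stage.
#' @param nested_fs with `"hybrid+fs"`, refit the selection inside every
#'   training fold (default, leakage-free).  `FALSE` selects once on the
#'   full matrix before CV -- optimistically biased, provided only for
#'   comparison with selection-then-validate protocols.
#' @return list of class `mi_experiment`: `report` (an `mi_eval`),
#'   `features` (the full [mi_features()] matrix), `selection` (an
#'   `mi_selection` for `"hybrid+fs"` runs: the full-data selection under
#'   `nested_fs = FALSE`, otherwise a bookkeeping selection refit on all
#'   trials), and `log` (resolved parameters, feature counts before/after
#'   selection, wall time per stage).
#' @export
run_experiment <- function(recording,
                           experiment = c("hybrid", "time-only", "wpd-only",
                                          "hybrid+fs"),
                           config = pipeline_config(),
                           nested_fs = TRUE) {
  experiment <- match.arg(experiment)
  stopifnot(inherits(recording, "eeg_recording"),
            inherits(config, "pipeline_config"))
  if (!nrow(recording$markers))
    stop_mibci("schema", "recording has no markers")
  log <- list(experiment = experiment, config = unclass(config))
  t0 <- proc.time()[["elapsed"]]
  epochs <- preprocess(recording, config)
  cs <- resolve_channel_set(config$channel_set %||% recording$channel_labels,
                            recording)
  log$channel_set <- cs$labels
  log$n_trials <- dim(epochs$data)[1]
  log$t_preprocess <- proc.time()[["elapsed"]] - t0

  t0 <- proc.time()[["elapsed"]]
  time_block <- if (experiment != "wpd-only")
    extract_time_features(epochs, cs, renyi_q = config$renyi_q) else NULL
  wpd_block <- if (experiment != "time-only")
    extract_wpd_features(epochs, cs, level = config$wpd_level,
                         wavelet = config$wavelet,
                         layout = config$wpd_layout) else NULL
  features <- fuse_features(time_block, wpd_block, epochs$labels)
  log$n_features <- ncol(features$X)
  log$t_extract <- proc.time()[["elapsed"]] - t0

  spec <- mi_classifier(config$classifier, cost = config$svm_cost,
                        k = config$knn_k)
  selection <- NULL
  selector <- NULL
  t0 <- proc.time()[["elapsed"]]
  if (experiment == "hybrid+fs") {
    if (nested_fs) {
      selector <- function(Xtr, ytr, seed)
        hybrid_select(Xtr, ytr, spec = spec,
                      inner_folds = config$cv_folds, seed = seed)$selected
    } else {
      selection <- hybrid_select(features$X, features$labels, spec = spec,
                                 inner_folds = config$cv_folds,
                                 seed = config$seed)
      log$n_features_after_fs <- length(selection$selected)
    }
  }
  X <- features$X
  if (!is.null(selection) && length(selection$selected))
    X <- X[, selection$selected, drop = FALSE]
  report <- crossvalidate(X, features$labels, spec = spec,
                          folds = config$cv_folds, seed = config$seed,
                          selector = selector)
  if (experiment == "hybrid+fs" && nested_fs)
    log$n_features_after_fs <- report$aggregate$mean_n_selected
  log$t_evaluate <- proc.time()[["elapsed"]] - t0

  structure(list(report = report, features = features, selection = selection,
                 log = log),
            class = "mi_experiment")
}

#' @export
print.mi_experiment <- function(x, ...) {
  cat(sprintf("<mi_experiment> %s: %d trials, %d features",
              x$log$experiment, x$log$n_trials, x$log$n_features))
  if (!is.null(x$log$n_features_after_fs))
    cat(sprintf(" -> %.1f after selection", x$log$n_features_after_fs))
  cat("\n")
  print(x$report)
  invisible(x)
}

#' Compare channel sets on one recording
#'
#' Runs the same experiment once per channel set and ranks the sets by mean
#' cross-validated accuracy.
#'
#' @param recording a marked [eeg_recording()].
#' @param sets non-empty list of channel-set names or label vectors.
#' @param experiment,config,nested_fs as in [run_experiment()].
#' @return list with `reports` (one `mi_experiment` per set) and `ranking`
#'   (data frame sorted by decreasing mean accuracy, with SD).
#' @export
compare_channel_sets <- function(recording, sets, experiment = "hybrid",
                                 config = pipeline_config(),
                                 nested_fs = TRUE) {
  if (!length(sets)) stop_mibci("parameter", "empty channel-set list")
  if (!is.list(sets)) sets <- as.list(sets)
  names(sets) <- vapply(seq_along(sets), function(i) {
    nm <- names(sets)[i]
    if (!is.null(nm) && nzchar(nm)) nm
    else if (length(sets[[i]]) == 1L) sets[[i]]
    else paste0("set", i)
  }, character(1))
  reports <- lapply(sets, function(s) {
    cfg <- config
    cfg$channel_set <- s
    run_experiment(recording, experiment, cfg, nested_fs = nested_fs)
  })
  ranking <- data.frame(
    set = names(sets),
    n_channels = vapply(reports, function(r) length(r$log$channel_set), integer(1)),
    mean_accuracy = vapply(reports, function(r)
      r$report$aggregate$mean[["accuracy"]], numeric(1)),
    sd_accuracy = vapply(reports, function(r)
      r$report$aggregate$sd[["accuracy"]], numeric(1)),
    row.names = NULL)
  ranking <- ranking[order(-ranking$mean_accuracy), ]
  list(reports = reports, ranking = ranking)
}
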