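# Cross-validated evaluation with the full two-class metric suite:
# accuracy, sensitivity, specificity, precision, F1 and AUC, per fold and
# aggregated.

#' Confusion counts of a prediction
#'
#' @param truth,predicted label vectors of equal length.
#' @param positive the positive class label.
#' @return named integer vector `c(TP, FN, TN, FP)`.
#' @export
confusion_counts <- function(truth, predicted, positive) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  c(TP = sum(truth == positive & predicted == positive),
    FN = sum(truth == positive & predicted != positive),
    TN = sum(truth != positive & predicted != positive),
    FP = sum(truth != positive & predicted == positive))
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and
#' `F1 = 2*precision*recall/(precision+recall)` with recall = sensitivity.
#' A metric whose denominator is zero is returned as `NA` (undefined), not
#' silently zero.
#'
#' @param counts named vector with `TP`, `FN`, `TN`, `FP`.
#' @return named numeric vector of the five metrics.
#' @export
classification_metrics <- function(counts) {
  TP <- counts[["TP"]]; FN <- counts[["FN"]]
  TN <- counts[["TN"]]; FP <- counts[["FP"]]
  if (any(c(TP, FN, TN, FP) < 0)) stop_mibci("parameter", "negative confusion counts")
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  acc <- safe(TP + TN, TP + TN + FP + FN)
  sens <- safe(TP, TP + FN)
  spec <- safe(TN, TN + FP)
  prec <- safe(TP, TP + FP)
  f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  c(accuracy = acc, sensitivity = sens, specificity = spec,
    precision = prec, f1 = f1)
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney statistic (equivalent to the
#' trapezoidal area under the ROC curve with tied scores contributing a
#' half): the probability that a random positive outscores a random
#' negative.
#'
#' @param scores numeric decision scores, larger = more positive.
#' @param y two-class labels.
#' @param positive the positive class; default the lexicographically larger
#'   label.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, y, positive = NULL) {
  y <- factor(y)
  if (nlevels(y) < 2L) stop_mibci("degenerate_label", "AUC undefined for a single class")
  if (any(!is.finite(scores))) stop_mibci("parameter", "scores must be finite")
  positive <- positive %||% sort(levels(y))[2L]
  pos <- y == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold cross-validated evaluation
#'
#' Folds are stratified within class from a seeded shuffle.  When a
#' `selector` is supplied, feature selection is refit inside every training
#' fold and only the fold's selected columns reach the classifier -- the
#' test fold never influences selection.
#'
#' @param X feature matrix (or an [mi_features()], in which case `y` is
#'   taken from it).
#' @param y two-class labels.
#' @param spec an [mi_classifier()].
#' @param folds number of folds (default 10).
#' @param seed RNG seed for the fold assignment (and passed to `selector`).
#' @param selector optional `function(X_train, y_train, seed)` returning
#'   integer column indices to keep (e.g. a wrapper around
#'   [hybrid_select()]).
#' @param positive positive class label override.
#' @return object of class `mi_eval`: `folds` (per-fold counts and
#'   metrics, plus `n_selected` when a selector ran), `aggregate` (mean and
#'   SD of each metric, pooled counts and pooled accuracy), `classifier`,
#'   `positive`, `seed`.
#' @export
crossvalidate <- function(X, y = NULL, spec = mi_classifier("svm-linear"),
                          folds = 10L, seed = 1L, selector = NULL,
                          positive = NULL) {
  if (inherits(X, "mi_features")) { y <- X$labels; X <- X$X }
  y <- factor(y)
  if (nlevels(y) != 2L) stop_mibci("degenerate_label", "need exactly two classes")
  if (nrow(X) < folds) stop_mibci("fold", "fewer trials than folds")
  positive <- positive %||% sort(levels(y))[2L]
  fold_id <- .stratified_folds(y, folds, seed)
  rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    Xtr <- X[!test, , drop = FALSE]; ytr <- y[!test]
    Xte <- X[test, , drop = FALSE]
    n_sel <- NA_integer_
    if (!is.null(selector)) {
      keep <- selector(Xtr, ytr, seed + f)
      if (!length(keep)) keep <- seq_len(ncol(Xtr))   # selector found nothing
      n_sel <- length(keep)
      Xtr <- Xtr[, keep, drop = FALSE]
      Xte <- Xte[, keep, drop = FALSE]
    }
    pred <- train_predict(Xtr, ytr, Xte, spec, positive = positive)
    cnt <- confusion_counts(y[test], pred$labels, positive)
    met <- classification_metrics(cnt)
    auc <- roc_auc(pred$scores, y[test], positive = positive)
    rows[[f]] <- data.frame(fold = f, t(cnt), t(met), auc = auc,
                            n_selected = n_sel)
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "sensitivity", "specificity", "precision",
                   "f1", "auc")
  agg <- list(
    mean = colMeans(per_fold[metric_cols], na.rm = TRUE),
    sd = apply(per_fold[metric_cols], 2L, stats::sd, na.rm = TRUE),
    counts = colSums(per_fold[c("TP", "FN", "TN", "FP")]),
    pooled_accuracy = sum(per_fold$TP + per_fold$TN) / nrow(X),
    n = nrow(X),
    mean_n_selected = if (!is.null(selector)) mean(per_fold$n_selected) else NA_real_)
  structure(list(folds = per_fold, aggregate = agg,
                 classifier = spec, positive = positive, seed = seed),
            class = "mi_eval")
}

#' @export
print.mi_eval <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<mi_eval> %s, %d folds, n = %d, positive = '%s'\n",
              x$classifier$kind, nrow(x$folds), a$n, x$positive))
  for (m in names(a$mean))
    cat(sprintf("  %-11s %.4f (SD %.4f)\n", m, a$mean[[m]], a$sd[[m]]))
  if (!is.na(a$mean_n_selected))
    cat(sprintf("  selected features per fold: %.1f (of %s)\n",
                a$mean_n_selected, "full set"))
  invisible(x)
}

#' Write an evaluation report as delimited text
#'
#' Per-fold table (TSV) plus a YAML aggregate block alongside it.
#'
#' @param report an `mi_eval`.
#' @param path base path; writes `<path>.tsv` and `<path>.yaml`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "mi_eval"))
  utils::write.table(report$folds, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  a <- report$aggregate
  yaml::write_yaml(list(classifier = report$classifier$kind,
                        positive = report$positive, seed = report$seed,
                        n = a$n,
                        mean = as.list(a$mean), sd = as.list(a$sd),
                        pooled_counts = as.list(a$counts),
                        pooled_accuracy = a$pooled_accuracy,
                        mean_n_selected = a$mean_n_selected),
                   paste0(path, ".yaml"))
  invisible(path)
}
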