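# Hybrid feature selection: a correlation-based filter (CFS) prunes the
# feature pool, then a classifier-wrapper forward stepwise search refines
# the survivors by cross-validated accuracy.

# binary labels as 0/1 with the positive class = lexicographically larger level
.binary_y <- function(y) {
  y <- factor(y)
  if (nlevels(y) != 2L)
    stop_mibci("degenerate_label", "need exactly two classes, got %d", nlevels(y))
  as.numeric(y == sort(levels(y))[2L])
}

#' CFS merit of a feature subset
#'
#' `merit = k * rcf / sqrt(k + k * (k - 1) * rff)` where `rcf` is the mean
#' absolute feature-class correlation (point-biserial against the binary
#' label) and `rff` the mean absolute pairwise Pearson feature-feature
#' correlation over the subset.  High merit rewards class-relevant,
#' mutually non-redundant subsets.
#'
#' @param subset integer indices of the candidate subset (non-empty).
#' @param X numeric feature matrix (trials x features).
#' @param y two-class label vector.
#' @return the merit (a non-negative scalar).
#' @export
cfs_merit <- function(subset, X, y) {
  if (!length(subset)) stop_mibci("empty_input", "empty subset has no merit")
  yb <- .binary_y(y)
  sub <- X[, subset, drop = FALSE]
  sds <- apply(sub, 2L, stats::sd)
  if (any(sds == 0))
    stop_mibci("undefined_correlation", "constant feature in subset: %s",
               paste(subset[sds == 0], collapse = ", "))
  rcf <- abs(as.vector(stats::cor(sub, yb)))
  k <- length(subset)
  sum_rff <- if (k > 1L) {
    cm <- abs(stats::cor(sub))
    sum(cm[upper.tri(cm)])
  } else 0
  sum(rcf) / sqrt(k + 2 * sum_rff)
}

#' CFS filter: best-first subset search
#'
#' Greedy best-first search over feature subsets maximizing [cfs_merit()],
#' starting from the empty set and expanding by single-feature additions.
#' The search stops after `patience` consecutive expansions that fail to
#' improve the best merit found (default 5, the canonical CFS stopping
#' rule).  Deterministic: ties are broken toward the lowest feature index.
#'
#' @param X numeric feature matrix.
#' @param y two-class labels.
#' @param patience consecutive non-improving expansions tolerated.
#' @param max_subset optional hard cap on the subset size explored.
#' @return list with `survivors` (integer indices of the best subset,
#'   ascending), and `merit_trace` (best merit after each expansion).
#' @export
cfs_filter <- function(X, y, patience = 5L, max_subset = Inf) {
  yb <- .binary_y(y)
  p <- ncol(X)
  sds <- apply(X, 2L, stats::sd)
  usable <- unname(which(sds > 0))
  if (!length(usable)) stop_mibci("no_signal", "all features are constant")
  rcf <- rep(0, p)
  rcf[usable] <- abs(as.vector(stats::cor(X[, usable, drop = FALSE], yb)))
  rcf[is.na(rcf)] <- 0
  if (p == 1L || length(usable) == 1L)
    return(list(survivors = usable[1L], merit_trace = rcf[usable[1L]]))

  # lazily-filled cache of |cor(feature i, feature j)| columns
  corr_cache <- new.env(parent = emptyenv())
  cor_col <- function(j) {
    key <- as.character(j)
    if (!is.null(corr_cache[[key]])) return(corr_cache[[key]])
    v <- rep(0, p)
    v[usable] <- abs(as.vector(stats::cor(X[, usable, drop = FALSE], X[, j])))
    v[j] <- 1
    v[is.na(v)] <- 0
    corr_cache[[key]] <- v
    v
  }
  merit_of <- function(sum_rcf, sum_rff, k) sum_rcf / sqrt(k + 2 * sum_rff)

  # node: list(idx, sum_rcf, sum_rff, merit)
  start <- {
    j <- usable[which.max(rcf[usable])]
    list(idx = j, sum_rcf = rcf[j], sum_rff = 0, merit = rcf[j])
  }
  best <- start
  open <- list(start)
  visited <- new.env(parent = emptyenv())
  assign(paste(start$idx, collapse = ","), TRUE, visited)
  stall <- 0L
  trace <- best$merit
  while (length(open) && stall < patience) {
    merits <- vapply(open, `[[`, numeric(1), "merit")
    pick <- which.max(merits)
    node <- open[[pick]]
    open[[pick]] <- NULL
    if (length(node$idx) >= min(max_subset, length(usable))) next
    # correlation of every feature with the members of this subset
    rff_add <- rep(0, p)
    for (m in node$idx) rff_add <- rff_add + cor_col(m)
    cand <- setdiff(usable, node$idx)
    k <- length(node$idx) + 1L
    cand_merit <- merit_of(node$sum_rcf + rcf[cand], node$sum_rff + rff_add[cand], k)
    improved <- FALSE
    ord <- order(cand_merit, -cand, decreasing = TRUE)   # ties -> lowest index
    for (ci in utils::head(ord, 5L)) {                   # queue a few best children
      j <- cand[ci]
      idx <- sort(c(node$idx, j))
      key <- paste(idx, collapse = ",")
      if (!is.null(visited[[key]])) next
      assign(key, TRUE, visited)
      child <- list(idx = idx, sum_rcf = node$sum_rcf + rcf[j],
                    sum_rff = node$sum_rff + rff_add[j],
                    merit = cand_merit[ci])
      open[[length(open) + 1L]] <- child
      if (child$merit > best$merit + 1e-12) {
        best <- child
        improved <- TRUE
      }
    }
    stall <- if (improved) 0L else stall + 1L
    trace <- c(trace, best$merit)
  }
  list(survivors = sort(best$idx), merit_trace = trace)
}

# stratified fold assignment: within each class, seeded shuffle then cycle
.stratified_folds <- function(y, folds, seed) {
  y <- factor(y)
  if (min(table(y)) < folds)
    stop_mibci("stratification",
               "cannot stratify %d folds: smallest class has %d trials",
               folds, min(table(y)))
  assign <- integer(length(y))
  with_seed(seed, {
    for (lv in levels(y)) {
      idx <- which(y == lv)
      assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  assign
}

# inner-CV accuracy of a classifier on X[, subset] with fixed folds
.subset_cv_accuracy <- function(X, y, subset, spec, fold_id) {
  folds <- max(fold_id)
  correct <- 0L
  for (f in seq_len(folds)) {
    test <- fold_id == f
    pred <- train_predict(X[!test, subset, drop = FALSE], y[!test],
                          X[test, subset, drop = FALSE], spec)
    correct <- correct + sum(pred$labels == y[test])
  }
  correct / length(y)
}

#' Wrapper forward feature selection
#'
#' Classifier-subset-evaluator search: starting from the empty model, each
#' round evaluates adding every remaining feature by the stratified
#' inner-CV accuracy of the configured classifier and accepts the best
#' strictly-improving addition (ties toward the lowest feature index).  The
#' search stops at the first round with no strict improvement, so the
#' accuracy trace is strictly increasing.  The empty-model baseline is the
#' majority-class rate.
#'
#' @param X numeric feature matrix (already restricted to filter survivors
#'   when used inside [hybrid_select()]).
#' @param y two-class labels.
#' @param spec an [mi_classifier()] (default linear SVM).
#' @param inner_folds folds for the inner CV (default 10).
#' @param seed RNG seed fixing the inner fold assignment.
#' @return object of class `mi_selection`: `selected` (indices in order of
#'   acceptance), `wrapper_trace` (inner-CV accuracy after each acceptance),
#'   `filter_survivors`, `merit_trace` (both `NULL` here; filled by
#'   [hybrid_select()]), and `config`.
#' @export
wrapper_forward_select <- function(X, y, spec = mi_classifier("svm-linear"),
                                   inner_folds = 10L, seed = 1L) {
  y <- factor(y)
  if (nlevels(y) != 2L) stop_mibci("degenerate_label", "need two classes")
  if (nrow(X) < inner_folds)
    stop_mibci("fold", "fewer samples (%d) than inner folds (%d)", nrow(X), inner_folds)
  fold_id <- .stratified_folds(y, inner_folds, seed)
  selected <- integer(0)
  trace <- numeric(0)
  current <- max(table(y)) / length(y)        # empty-model baseline
  remaining <- seq_len(ncol(X))
  repeat {
    if (!length(remaining)) break
    accs <- vapply(remaining, function(j)
      .subset_cv_accuracy(X, y, c(selected, j), spec, fold_id), numeric(1))
    best <- which.max(accs)                    # which.max takes first = lowest index
    if (accs[best] <= current + 1e-12) break
    current <- accs[best]
    selected <- c(selected, remaining[best])
    trace <- c(trace, current)
    remaining <- remaining[-best]
  }
  structure(list(selected = selected, filter_survivors = NULL,
                 merit_trace = NULL, wrapper_trace = trace,
                 config = list(classifier = spec$kind,
                               inner_folds = inner_folds, seed = seed),
                 n_features = ncol(X), feature_names = colnames(X)),
            class = "mi_selection")
}

#' Hybrid filter + wrapper feature selection
#'
#' The CFS filter ([cfs_filter()]) first prunes the feature pool; the
#' wrapper ([wrapper_forward_select()]) then forward-selects among the
#' survivors.  Deterministic given `(X, y, seed)`.
#'
#' @inheritParams wrapper_forward_select
#' @param patience CFS best-first stopping patience.
#' @return an `mi_selection` with `selected` expressed in the original
#'   column indices of `X`, plus `filter_survivors` and both search traces.
#' @export
hybrid_select <- function(X, y, spec = mi_classifier("svm-linear"),
                          inner_folds = 10L, seed = 1L, patience = 5L) {
  if (inherits(X, "mi_features")) { y <- X$labels; X <- X$X }
  filt <- cfs_filter(X, y, patience = patience)
  wr <- wrapper_forward_select(X[, filt$survivors, drop = FALSE], y,
                               spec = spec, inner_folds = inner_folds,
                               seed = seed)
  structure(list(selected = filt$survivors[wr$selected],
                 filter_survivors = filt$survivors,
                 merit_trace = filt$merit_trace,
                 wrapper_trace = wr$wrapper_trace,
                 config = wr$config,
                 n_features = ncol(X), feature_names = colnames(X)),
            class = "mi_selection")
}

#' @export
print.mi_selection <- function(x, ...) {
  cat(sprintf("<mi_selection> %d selected / %s survivors / %d features (%s)\n",
              length(x$selected),
              if (is.null(x$filter_survivors)) "-" else length(x$filter_survivors),
              x$n_features, x$config$classifier))
  if (length(x$wrapper_trace))
    cat("  wrapper accuracy trace:",
        paste(sprintf("%.3f", x$wrapper_trace), collapse = " -> "), "\n")
  if (length(x$selected) && !is.null(x$feature_names))
    cat("  selected:", paste(utils::head(x$feature_names[x$selected], 6),
                             collapse = ", "),
        if (length(x$selected) > 6) "..." else "", "\n")
  invisible(x)
}

#' Serialize a selection result to structured text
#'
#' @param selection an `mi_selection`.
#' @param path output YAML path.
#' @export
write_selection <- function(selection, path) {
  stopifnot(inherits(selection, "mi_selection"))
  yaml::write_yaml(list(
    selected = as.integer(selection$selected),
    selected_names = if (!is.null(selection$feature_names))
      as.list(selection$feature_names[selection$selected]) else NULL,
    filter_survivors = as.integer(selection$filter_survivors),
    merit_trace = as.numeric(selection$merit_trace),
    wrapper_trace = as.numeric(selection$wrapper_trace),
    config = selection$config,
    n_features = selection$n_features), path)
  invisible(path)
}
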