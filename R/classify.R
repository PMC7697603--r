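# Classifier backends: linear-kernel SVM (e1071), LDA (MASS, with a ridge
# fallback when the pooled covariance is singular), and Euclidean k-NN
# (class).  All three return hard labels plus a continuous score per test
# row, oriented so that larger scores favor the positive class, which keeps
# ROC/AUC consistent across backends.

#' Classifier specification
#'
#' @param kind `"svm-linear"`, `"lda"`, or `"knn"`.
#' @param cost linear-SVM regularization constant (default 1).
#' @param k k-NN neighbor count; must be odd so two-class votes cannot tie.
#' @return object of class `mi_classifier`.
#' @export
mi_classifier <- function(kind = c("svm-linear", "lda", "knn"), cost = 1, k = 5L) {
  kind <- match.arg(kind)
  if (!is_count(k) || k %% 2L == 0L)
    stop_mibci("parameter", "k must be an odd positive integer")
  structure(list(kind = kind, cost = cost, k = as.integer(k)),
            class = "mi_classifier")
}

# standardize by training statistics; constant columns pass through centered
.standardize_pair <- function(train_X, test_X) {
  mu <- colMeans(train_X)
  sdev <- apply(train_X, 2L, stats::sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  list(train = sweep(sweep(train_X, 2L, mu), 2L, sdev, "/"),
       test = sweep(sweep(test_X, 2L, mu), 2L, sdev, "/"))
}

# ridge-regularized pooled-covariance LDA, used when MASS::lda cannot fit
.ridge_lda <- function(train_X, yf, test_X, positive) {
  lv <- levels(yf)
  mus <- lapply(lv, function(l) colMeans(train_X[yf == l, , drop = FALSE]))
  ctr <- train_X
  for (l in lv) ctr[yf == l, ] <- sweep(train_X[yf == l, , drop = FALSE], 2L, mus[[match(l, lv)]])
  S <- crossprod(ctr) / (nrow(train_X) - length(lv))
  lambda <- 1e-3 * mean(diag(S)) + 1e-12
  S <- S + diag(lambda, ncol(S))
  w <- solve(S, mus[[2L]] - mus[[1L]])
  thresh <- sum(w * (mus[[1L]] + mus[[2L]])) / 2 +
    log(sum(yf == lv[1L]) / sum(yf == lv[2L]))
  score2 <- as.vector(test_X %*% w) - thresh   # > 0 favors lv[2]
  pred <- factor(ifelse(score2 > 0, lv[2L], lv[1L]), levels = lv)
  score <- if (positive == lv[2L]) score2 else -score2
  list(labels = pred, scores = score)
}

#' Train a classifier and predict test labels and scores
#'
#' Features are standardized by the training-fold mean and SD before
#' fitting.  Scores: SVM, signed distance to the separating hyperplane;
#' LDA, posterior-probability difference; k-NN, fraction of neighbors
#' voting for the positive class.  All are oriented toward `positive`.
#'
#' @param train_X,train_y training features (matrix) and two-class labels.
#' @param test_X test features.
#' @param spec an [mi_classifier()].
#' @param positive label of the positive class; default the
#'   lexicographically larger one.
#' @return list with `labels` (factor over the training levels) and
#'   `scores` (numeric, one per test row).
#' @export
train_predict <- function(train_X, train_y, test_X,
                          spec = mi_classifier("svm-linear"),
                          positive = NULL) {
  stopifnot(inherits(spec, "mi_classifier"))
  yf <- factor(train_y)
  if (nlevels(yf) != 2L)
    stop_mibci("degenerate_fold", "training fold has %d class(es); need 2", nlevels(yf))
  positive <- positive %||% sort(levels(yf))[2L]
  if (!positive %in% levels(yf)) stop_mibci("parameter", "unknown positive class '%s'", positive)
  train_X <- as.matrix(train_X); test_X <- as.matrix(test_X)
  z <- .standardize_pair(train_X, test_X)

  if (spec$kind == "svm-linear") {
    fit <- e1071::svm(z$train, yf, kernel = "linear", cost = spec$cost,
                      scale = FALSE)
    pr <- stats::predict(fit, z$test, decision.values = TRUE)
    dv <- as.vector(attr(pr, "decision.values"))
    # e1071 orients the decision value toward the first level of its label
    # pair; flip so larger = positive class
    dv_pos <- sub("/.*$", "", colnames(attr(pr, "decision.values")))
    score <- if (dv_pos == positive) dv else -dv
    return(list(labels = factor(pr, levels = levels(yf)), scores = score))
  }
  if (spec$kind == "lda") {
    fit <- tryCatch(
      suppressWarnings(MASS::lda(z$train, grouping = yf)),
      error = function(e) NULL)
    if (is.null(fit)) {
      message("LDA covariance singular; using ridge-regularized LDA")
      return(.ridge_lda(z$train, yf, z$test, positive))
    }
    pr <- stats::predict(fit, z$test)
    post <- pr$posterior
    score <- post[, positive] - post[, setdiff(levels(yf), positive)]
    return(list(labels = factor(pr$class, levels = levels(yf)),
                scores = as.vector(score)))
  }
  # knn
  k <- min(spec$k, nrow(z$train))
  if (k %% 2L == 0L) k <- k - 1L
  pr <- class::knn(z$train, z$test, yf, k = k, prob = TRUE, use.all = TRUE)
  win_frac <- attr(pr, "prob")
  score <- ifelse(pr == positive, win_frac, 1 - win_frac)
  list(labels = factor(pr, levels = levels(yf)), scores = as.vector(score))
}
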