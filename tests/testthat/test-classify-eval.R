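make_blobs <- function(n = 60, d = 2, sep = 6, seed = 1L) {
  mibci:::with_seed(seed, {
    y <- rep(c("a", "b"), length.out = n)
    X <- matrix(rnorm(n * d), n, d)
    X[y == "b", 1] <- X[y == "b", 1] + sep
    colnames(X) <- paste0("f", seq_len(d))
    list(X = X, y = factor(y))
  })
}

test_that("all three classifiers separate linearly separable blobs", {
  bl <- make_blobs(seed = 2L)
  tr <- seq_len(40); te <- 41:60
  for (kind in c("svm-linear", "lda", "knn")) {
    p <- train_predict(bl$X[tr, ], bl$y[tr], bl$X[te, ], mi_classifier(kind))
    expect_identical(as.character(p$labels), as.character(bl$y[te]))
    expect_equal(roc_auc(p$scores, bl$y[te]), 1.0)
  }
})

test_that("1-NN returns the label of an exactly matching training point", {
  bl <- make_blobs(seed = 3L)
  p <- train_predict(bl$X, bl$y, bl$X[c(5, 12), , drop = FALSE],
                     mi_classifier("knn", k = 1L))
  expect_identical(as.character(p$labels), as.character(bl$y[c(5, 12)]))
})

test_that("label-permuted training data scores at chance", {
  bl <- make_blobs(n = 400, sep = 4, seed = 4L)
  yperm <- mibci:::with_seed(5, sample(bl$y))
  tr <- seq_len(200); te <- 201:400
  p <- train_predict(bl$X[tr, ], yperm[tr], bl$X[te, ], mi_classifier("svm-linear"))
  acc <- mean(p$labels == yperm[te])
  ci <- 1.96 * sqrt(0.25 / 200)
  expect_gt(acc, 0.5 - ci); expect_lt(acc, 0.5 + ci)
})

test_that("single-class training folds are rejected", {
  bl <- make_blobs(seed = 6L)
  expect_error(train_predict(bl$X[bl$y == "a", ], bl$y[bl$y == "a"], bl$X,
                             mi_classifier("lda")),
               class = "mibci_degenerate_fold")
})

test_that("LDA falls back to ridge regularization on singular covariance", {
  bl <- make_blobs(n = 20, d = 2, seed = 7L)
  X <- cbind(bl$X, dup1 = bl$X[, 1], dup2 = bl$X[, 1])  # rank-deficient
  expect_no_error({
    p <- train_predict(X[1:14, ], bl$y[1:14], X[15:20, ], mi_classifier("lda"))
  })
  expect_length(p$labels, 6L)
  expect_true(all(is.finite(p$scores)))
})

test_that("metric suite matches hand arithmetic on the contingency table", {
  m <- classification_metrics(c(TP = 9, FN = 1, TN = 8, FP = 2))
  expect_equal(unname(m["accuracy"]), 0.85)
  expect_equal(unname(m["sensitivity"]), 0.90)
  expect_equal(unname(m["specificity"]), 0.80)
  expect_equal(unname(m["precision"]), 9 / 11, tolerance = 1e-12)
  expect_equal(unname(m["f1"]), 2 * (9 / 11) * 0.9 / (9 / 11 + 0.9),
               tolerance = 1e-12)

  perfect <- classification_metrics(c(TP = 5, FN = 0, TN = 7, FP = 0))
  expect_equal(unname(perfect), rep(1, 5))

  half <- classification_metrics(c(TP = 3, FN = 3, TN = 4, FP = 4))
  expect_equal(unname(half["accuracy"]), 0.5)

  undef <- classification_metrics(c(TP = 0, FN = 0, TN = 5, FP = 0))
  expect_true(is.na(undef["sensitivity"]))   # undefined, not silently 0
  expect_true(is.na(undef["precision"]))
})

test_that("AUC equals exhaustive pair counting and is anti-symmetric", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c("n", "n", "p", "p")), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10), c("n", "n", "p", "p")), 1.0)
  for (s in 1:10) {
    n <- mibci:::with_seed(s, sample(6:20, 1))
    y <- mibci:::with_seed(s + 50, sample(c("n", "p"), n, replace = TRUE,
                                          prob = c(0.5, 0.5)))
    if (length(unique(y)) < 2) next
    scores <- mibci:::with_seed(s + 100, round(rnorm(n), 1))  # induce ties
    auc <- roc_auc(scores, y)
    expect_equal(auc, bf_auc(scores, y, "p"), tolerance = 1e-12)
    expect_equal(roc_auc(-scores, y), 1 - auc, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep("p", 4)), class = "mibci_degenerate_label")
})

test_that("AUC agrees with an established ROC implementation", {
  y <- mibci:::with_seed(60, sample(c("n", "p"), 50, replace = TRUE))
  scores <- mibci:::with_seed(61, rnorm(50) + (y == "p"))
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = scores,
                                        levels = c("n", "p"), quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, y), ref, tolerance = 1e-12)
})

test_that("cross-validation is stratified, deterministic and aggregates counts", {
  bl <- make_blobs(n = 80, sep = 1.5, seed = 8L)
  r1 <- crossvalidate(bl$X, bl$y, folds = 10L, seed = 9L)
  r2 <- crossvalidate(bl$X, bl$y, folds = 10L, seed = 9L)
  expect_identical(r1$folds, r2$folds)
  # every fold contains both classes: TP+FN > 0 and TN+FP > 0
  expect_true(all(r1$folds$TP + r1$folds$FN > 0))
  expect_true(all(r1$folds$TN + r1$folds$FP > 0))
  # aggregate accuracy identity
  expect_equal(r1$aggregate$pooled_accuracy,
               sum(r1$folds$TP + r1$folds$TN) / 80)
  expect_equal(sum(r1$aggregate$counts), 80)
  # independent recomputation of fold metrics from stored counts
  for (f in c(1L, 6L)) {
    row <- r1$folds[f, ]
    m <- classification_metrics(c(TP = row$TP, FN = row$FN,
                                  TN = row$TN, FP = row$FP))
    expect_equal(row$accuracy, unname(m["accuracy"]))
    expect_equal(row$f1, unname(m["f1"]))
  }
})

test_that("degenerate fold requests raise stratification errors", {
  bl <- make_blobs(n = 10, seed = 10L)
  expect_error(crossvalidate(bl$X, bl$y, folds = 10L, seed = 1L),
               class = "mibci_stratification")
})

test_that("a fold-nested selector sees only its training fold", {
  bl <- make_blobs(n = 60, sep = 6, seed = 11L)
  seen <- integer(0)
  sel <- function(X, y, seed) { seen <<- c(seen, nrow(X)); 1L }
  r <- crossvalidate(bl$X, bl$y, folds = 5L, seed = 2L, selector = sel)
  expect_identical(seen, rep(48L, 5L))
  expect_equal(r$aggregate$mean_n_selected, 1)
  expect_equal(unname(r$aggregate$mean["accuracy"]), 1.0)
})

test_that("reports serialize to a per-fold table and aggregate block", {
  bl <- make_blobs(n = 40, seed = 12L)
  r <- crossvalidate(bl$X, bl$y, folds = 5L, seed = 3L)
  base <- tempfile()
  write_report(r, base)
  tab <- utils::read.table(paste0(base, ".tsv"), header = TRUE, sep = "\t")
  expect_identical(nrow(tab), 5L)
  agg <- yaml::read_yaml(paste0(base, ".yaml"))
  expect_equal(agg$mean$accuracy, unname(r$aggregate$mean["accuracy"]))
})
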