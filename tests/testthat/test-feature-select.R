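# constructed two-class fixture: `informative` columns shift with the class
make_fs_fixture <- function(n = 200, p = 10, informative = 1L, shift = 2,
                            seed = 1L) {
  mibci:::with_seed(seed, {
    y <- rep(c("a", "b"), length.out = n)
    X <- matrix(rnorm(n * p), n, p)
    for (j in informative) X[y == "b", j] <- X[y == "b", j] + shift
    colnames(X) <- sprintf("f%02d", seq_len(p))
    list(X = X, y = y)
  })
}

test_that("CFS merit follows the closed-form on hand-built structures", {
  fx <- make_fs_fixture(n = 400, shift = 1.5, seed = 2L)
  # single feature: merit reduces to the feature-class correlation
  rcf1 <- abs(cor(fx$X[, 1], as.numeric(fx$y == "b")))
  expect_equal(cfs_merit(1L, fx$X, fx$y), rcf1, tolerance = 1e-12)

  # duplicated feature: full redundancy gives no merit gain
  X2 <- cbind(a = fx$X[, 1], b = fx$X[, 1])
  expect_equal(cfs_merit(1:2, X2, fx$y), rcf1, tolerance = 1e-10)

  # closed form on arbitrary subsets
  yb <- as.numeric(fx$y == "b")
  rcf <- abs(as.vector(cor(fx$X, yb)))
  rff <- abs(cor(fx$X))
  for (sub in list(1:3, c(2L, 7L), c(1L, 4L, 8L, 10L)))
    expect_equal(cfs_merit(sub, fx$X, fx$y), bf_cfs_merit(rcf, rff, sub),
                 tolerance = 1e-12)

  # independence of the class drives merit toward zero
  noise <- make_fs_fixture(n = 2000, informative = integer(0), seed = 3L)
  expect_lt(cfs_merit(1L, noise$X, noise$y), 0.08)

  expect_error(cfs_merit(1L, cbind(f = rep(1, 10)), rep(c("a", "b"), 5)),
               class = "mibci_undefined_correlation")
})

test_that("CFS best-first search finds the exhaustive-merit optimum", {
  fx <- make_fs_fixture(n = 200, p = 10, informative = 1L, shift = 3, seed = 4L)
  res <- cfs_filter(fx$X, fx$y)
  expect_true(1L %in% res$survivors)
  # exhaustive maximization over all 2^10 - 1 subsets
  best_merit <- -Inf; best_sub <- NULL
  for (mask in 1:(2^10 - 1)) {
    sub <- which(bitwAnd(mask, 2^(0:9)) > 0)
    m <- cfs_merit(sub, fx$X, fx$y)
    if (m > best_merit) { best_merit <- m; best_sub <- sub }
  }
  expect_equal(cfs_merit(res$survivors, fx$X, fx$y), best_merit,
               tolerance = 1e-10)
  expect_identical(res$survivors, best_sub)
})

test_that("CFS keeps at most one of a duplicated informative pair", {
  fx <- make_fs_fixture(n = 200, p = 6, informative = 1L, shift = 3, seed = 5L)
  X <- cbind(fx$X, dup = fx$X[, 1])
  res <- cfs_filter(X, fx$y)
  expect_lte(sum(c(1L, 7L) %in% res$survivors), 1L)
})

test_that("single-feature input survives trivially", {
  fx <- make_fs_fixture(p = 1, seed = 6L)
  expect_identical(cfs_filter(fx$X, fx$y)$survivors, 1L)
  expect_error(cfs_filter(matrix(1, 10, 3), rep(c("a", "b"), 5)),
               class = "mibci_no_signal")
})

test_that("wrapper selects a separating feature and stops at perfection", {
  fx <- make_fs_fixture(n = 60, p = 6, informative = 1:2, shift = 8, seed = 7L)
  sel <- wrapper_forward_select(fx$X, fx$y, inner_folds = 5L, seed = 1L)
  expect_gte(length(sel$selected), 1L)
  expect_true(any(sel$selected %in% 1:2))
  expect_equal(utils::tail(sel$wrapper_trace, 1), 1.0)
  # strictly increasing trace by construction
  expect_true(all(diff(sel$wrapper_trace) > 0) || length(sel$wrapper_trace) <= 1)
})

test_that("wrapper on pure noise stays at chance", {
  fx <- make_fs_fixture(n = 200, p = 8, informative = integer(0), seed = 8L)
  sel <- wrapper_forward_select(fx$X, fx$y, inner_folds = 10L, seed = 2L)
  final <- if (length(sel$wrapper_trace)) utils::tail(sel$wrapper_trace, 1) else 0.5
  ci <- 1.96 * sqrt(0.25 / 200)
  expect_lt(final, 0.5 + 2 * ci)   # noise can only overfit a little
})

test_that("wrapper greedy path matches a naive reference on small problems", {
  for (s in 1:3) {
    fx <- make_fs_fixture(n = 60, p = 4, informative = 1L, shift = 1.2,
                          seed = 20L + s)
    spec <- mi_classifier("knn", k = 3L)
    sel <- wrapper_forward_select(fx$X, fx$y, spec = spec, inner_folds = 5L,
                                  seed = s)
    fold_id <- mibci:::.stratified_folds(factor(fx$y), 5L, s)
    ref <- bf_forward_select(fx$X, factor(fx$y), spec, fold_id)
    expect_identical(sel$selected, ref)
  }
})

test_that("hybrid selection is deterministic and respects the subset chain", {
  fx <- make_fs_fixture(n = 100, p = 20, informative = c(1L, 5L), shift = 2.5,
                        seed = 9L)
  s1 <- hybrid_select(fx$X, fx$y, inner_folds = 5L, seed = 3L)
  s2 <- hybrid_select(fx$X, fx$y, inner_folds = 5L, seed = 3L)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$wrapper_trace, s2$wrapper_trace)
  expect_true(all(s1$selected %in% s1$filter_survivors))
  expect_lte(length(s1$selected), length(s1$filter_survivors))
})

test_that("hybrid selection prunes a wide matrix to the informative core", {
  # wide fused matrix from the generator with 2 informative channels
  rec <- generate_recording(synth_config(
    30L, informative_channels = c(2L, 5L), effect = 1, seed = 11L))
  ep <- preprocess(rec, pipeline_config())
  fm <- fuse_features(extract_time_features(ep), extract_wpd_features(ep),
                      ep$labels)
  expect_identical(ncol(fm$X), 1836L)
  sel <- hybrid_select(fm, seed = 4L)
  expect_lt(length(sel$selected), 100L)
  chans <- sub("^CH:([^|]+)\\|.*$", "\\1", colnames(fm$X)[sel$selected])
  expect_true(any(chans %in% c("C3", "C4")))
})

test_that("selection results serialize to structured text", {
  fx <- make_fs_fixture(n = 60, p = 5, seed = 10L)
  sel <- hybrid_select(fx$X, fx$y, inner_folds = 5L, seed = 1L)
  path <- tempfile(fileext = ".yaml")
  write_selection(sel, path)
  back <- yaml::read_yaml(path)
  expect_identical(as.integer(back$selected), sel$selected)
  expect_identical(back$config$classifier, "svm-linear")
})
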