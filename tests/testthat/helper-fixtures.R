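# shared fixtures and independent oracles for the test suite

# deterministic small recording: sinusoids + seeded noise, optional markers
test_recording <- function(n_ch = 3L, n_samp = 1000L, fs = 100,
                           labels = c("C3", "Cz", "C4")[seq_len(n_ch)],
                           markers = NULL, seed = 1L) {
  data <- mibci:::with_seed(seed, {
    t(sapply(seq_len(n_ch), function(i)
      sin(2 * pi * (8 + 3 * i) * (seq_len(n_samp) - 1) / fs) +
        0.3 * rnorm(n_samp)))
  })
  eeg_recording(data, fs, labels, markers)
}

# marker frame with n alternating-class cues spaced evenly
test_markers <- function(n, spacing, offset = 1L,
                         classes = c("foot", "right_hand")) {
  data.frame(sample = offset + (seq_len(n) - 1L) * spacing,
             label = rep(classes, length.out = n),
             stringsAsFactors = FALSE)
}

# amplitude of a pure-frequency component via the FFT peak
fft_amplitude <- function(y, fs, freq) {
  n <- length(y)
  bin <- round(freq / fs * n) + 1L
  2 * Mod(stats::fft(y))[bin] / n
}

# brute-force Hjorth oracles (population variance, first differences)
bf_mobility <- function(y) {
  pv <- function(x) mean((x - mean(x))^2)
  sqrt(pv(diff(y)) / pv(y))
}
bf_complexity <- function(y) bf_mobility(diff(y)) / bf_mobility(y)

# exhaustive pair-counting AUC (ties count a half)
bf_auc <- function(scores, y, positive) {
  pos <- which(y == positive); neg <- which(y != positive)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

# naive forward stepwise selection sharing only the fold assignment and the
# classifier backend with the implementation under test
bf_forward_select <- function(X, y, spec, fold_id) {
  cv_acc <- function(cols) {
    hits <- 0L
    for (f in sort(unique(fold_id))) {
      te <- fold_id == f
      p <- train_predict(X[!te, cols, drop = FALSE], y[!te],
                         X[te, cols, drop = FALSE], spec)
      hits <- hits + sum(p$labels == y[te])
    }
    hits / length(y)
  }
  sel <- integer(0); best <- max(table(y)) / length(y)
  pool <- seq_len(ncol(X))
  repeat {
    if (!length(pool)) break
    accs <- sapply(pool, function(j) cv_acc(c(sel, j)))
    b <- which.max(accs)
    if (accs[b] <= best + 1e-12) break
    best <- accs[b]; sel <- c(sel, pool[b]); pool <- pool[-b]
  }
  sel
}

# closed-form CFS merit from precomputed correlation sums
bf_cfs_merit <- function(rcf, rff_mat, subset) {
  k <- length(subset)
  sum_rcf <- sum(rcf[subset])
  sum_rff <- if (k > 1) sum(rff_mat[subset, subset][upper.tri(diag(k))]) else 0
  sum_rcf / sqrt(k + 2 * sum_rff)
}

# Welch-style band power of one epoch (periodogram integral over a band)
band_power <- function(y, fs, low, high) {
  n <- length(y)
  p <- Mod(stats::fft(y))^2 / n^2
  freq <- (seq_len(n) - 1L) / n * fs
  sum(p[freq >= low & freq <= high & freq <= fs / 2]) * 2
}
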