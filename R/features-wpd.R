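# Feature set 2: six statistics per terminal wavelet packet sub-band --
# absolute mean, average power, standard deviation, adjacent-band
# absolute-mean ratio, skewness and kurtosis (higher-order statistics).
# With the default 4-level tree this gives 96 columns per channel, and
# 6 + 96 = 102 per channel once fused with the time block.

.wpd_stat_order <- c("mu", "pav", "sigma", "gamma", "skew", "kurt")

#' Six statistics of each wavelet packet sub-band
#'
#' For each node `i` (frequency-ascending) computes the absolute mean
#' `mu = mean(|x|)`, average power `pav = mean(x^2)`, population standard
#' deviation `sigma`, the adjacent-band ratio `gamma_i = mu_i / mu_{i+1}`
#' (closed cyclically, so the last node is compared with the first),
#' skewness and non-excess kurtosis (population standardized 3rd and 4th
#' moments).
#'
#' @param nodes a `wpd_nodes` object from [wpd_decompose()], or a plain list
#'   of numeric coefficient vectors in frequency order.
#' @return data frame with one row per sub-band and columns
#'   `mu, pav, sigma, gamma, skew, kurt`.
#' @export
subband_stats <- function(nodes) {
  vecs <- if (inherits(nodes, "wpd_nodes")) nodes$nodes else nodes
  if (!length(vecs) || any(!lengths(vecs)))
    stop_mibci("empty_input", "every sub-band must be non-empty")
  mu <- vapply(vecs, function(x) mean(abs(x)), numeric(1))
  pav <- vapply(vecs, function(x) mean(x^2), numeric(1))
  sigma <- vapply(vecs, pop_sd, numeric(1))
  if (any(mu <= 0))
    stop_mibci("ratio_degenerate", "sub-band with zero absolute mean; gamma undefined")
  gamma <- mu / mu[c(seq_along(mu)[-1L], 1L)]
  if (any(sigma <= 0))
    stop_mibci("moment_degenerate", "sub-band with zero variance; skew/kurt undefined")
  skew <- mapply(function(x, m, s) mean((x - m)^3) / s^3,
                 vecs, lapply(vecs, mean), sigma)
  kurt <- mapply(function(x, m, s) mean((x - m)^4) / s^4,
                 vecs, lapply(vecs, mean), sigma)
  data.frame(mu = mu, pav = pav, sigma = sigma, gamma = gamma,
             skew = skew, kurt = kurt)
}

#' Extract the wavelet packet feature block
#'
#' Decomposes every trial and channel with a `level`-deep wavelet packet
#' transform and computes the six sub-band statistics.  Columns are
#' channel-major, node-ascending within channel (frequency order, sub-band
#' tags `b01..b16` at level 4), statistics ordered
#' mu, pav, sigma, gamma, skew, kurt, and named
#' `CH:<label>|wpd|<subband>|<stat>`.
#'
#' The `"adjacent-gamma-plus-activity"` layout instead emits one gamma per
#' interior adjacency (`2^level - 1` ratios) plus a per-channel Hjorth
#' activity column, for the same total width.
#'
#' @param epochs an `eeg_epochs` object.
#' @param channel_set channel set (as in [extract_time_features()]).
#' @param level decomposition depth (default 4).
#' @param wavelet wavelet family (default `"db4"`).
#' @param layout `"cyclic-gamma"` (default) or
#'   `"adjacent-gamma-plus-activity"`.
#' @return numeric matrix, trials x (6 * 2^level * channels) under the
#'   default layout.
#' @export
extract_wpd_features <- function(epochs, channel_set = NULL, level = 4L,
                                 wavelet = "db4",
                                 layout = c("cyclic-gamma",
                                            "adjacent-gamma-plus-activity")) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  layout <- match.arg(layout)
  ch_labels <- .resolve_epoch_channels(epochs, channel_set)
  ch_idx <- match(ch_labels, epochs$channel_labels)
  f <- wavelet_filter(wavelet)
  n_trial <- dim(epochs$data)[1]
  n_node <- 2^level
  blocks <- vector("list", length(ch_labels))
  for (ci in seq_along(ch_idx)) {
    X <- epochs$data[, ch_idx[ci], , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, nrow = n_trial)
    nodes <- .wpd_decompose_rows(X, level, f)   # list of trials x coef matrices
    mu <- sapply(nodes, function(m) rowMeans(abs(m)))
    pav <- sapply(nodes, function(m) rowMeans(m^2))
    if (n_trial == 1L) { mu <- rbind(mu); pav <- rbind(pav) }
    ctr <- lapply(nodes, function(m) m - rowMeans(m))
    v2 <- sapply(ctr, function(m) rowMeans(m^2))
    if (n_trial == 1L) v2 <- rbind(v2)
    sigma <- sqrt(v2)
    if (any(mu <= 0) || any(sigma <= 0))
      stop_mibci("moment_degenerate",
                 "degenerate sub-band (zero mean amplitude or variance) on channel %s",
                 ch_labels[ci])
    skew <- sapply(seq_len(n_node), function(i) rowMeans(ctr[[i]]^3) / sigma[, i]^3)
    kurt <- sapply(seq_len(n_node), function(i) rowMeans(ctr[[i]]^4) / sigma[, i]^4)
    if (n_trial == 1L) { skew <- rbind(skew); kurt <- rbind(kurt) }
    if (layout == "cyclic-gamma") {
      gam <- mu / mu[, c(seq_len(n_node)[-1L], 1L), drop = FALSE]
      stats <- list(mu = mu, pav = pav, sigma = sigma, gamma = gam,
                    skew = skew, kurt = kurt)
      tags <- sprintf("b%02d", seq_len(n_node))
      block <- matrix(NA_real_, n_trial, n_node * 6L)
      nm <- character(n_node * 6L)
      col <- 0L
      for (b in seq_len(n_node)) for (st in .wpd_stat_order) {
        col <- col + 1L
        block[, col] <- stats[[st]][, b]
        nm[col] <- .feat_name(ch_labels[ci], "wpd", tags[b], st)
      }
    } else {
      # five stats per node + interior adjacent ratios + Hjorth activity
      gam <- mu[, -n_node, drop = FALSE] / mu[, -1L, drop = FALSE]
      act <- apply(X, 1L, hjorth_activity)
      stats5 <- list(mu = mu, pav = pav, sigma = sigma, skew = skew, kurt = kurt)
      tags <- sprintf("b%02d", seq_len(n_node))
      ncol_block <- n_node * 5L + (n_node - 1L) + 1L
      block <- matrix(NA_real_, n_trial, ncol_block)
      nm <- character(ncol_block)
      col <- 0L
      for (b in seq_len(n_node)) for (st in c("mu", "pav", "sigma", "skew", "kurt")) {
        col <- col + 1L
        block[, col] <- stats5[[st]][, b]
        nm[col] <- .feat_name(ch_labels[ci], "wpd", tags[b], st)
      }
      for (b in seq_len(n_node - 1L)) {
        col <- col + 1L
        block[, col] <- gam[, b]
        nm[col] <- .feat_name(ch_labels[ci], "wpd",
                              sprintf("b%02d-b%02d", b, b + 1L), "gamma")
      }
      col <- col + 1L
      block[, col] <- act
      nm[col] <- .feat_name(ch_labels[ci], "time", "NA", "activity")
    }
    colnames(block) <- nm
    blocks[[ci]] <- block
  }
  do.call(cbind, blocks)
}

#' Construct a labeled feature matrix
#'
#' @param X numeric matrix, trials x features, with unique column names.
#' @param labels per-trial class labels (two classes).
#' @return object of class `mi_features`.
#' @export
mi_features <- function(X, labels) {
  if (!is.matrix(X) || is.null(colnames(X)) || anyDuplicated(colnames(X)))
    stop_mibci("schema", "X must be a matrix with unique column names")
  labels <- factor(labels)
  if (length(labels) != nrow(X))
    stop_mibci("alignment", "labels length (%d) != trial count (%d)",
               length(labels), nrow(X))
  if (nlevels(labels) > 2L)
    stop_mibci("unsupported_task", "more than two classes")
  structure(list(X = X, labels = labels), class = "mi_features")
}

#' @export
print.mi_features <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<mi_features> %d trials x %d features (%s)\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.mi_features <- function(x) dim(x$X)

#' Fuse the time and wavelet packet feature blocks
#'
#' Horizontal concatenation with the time block first.  Under the default
#' layout the fused width is `channels * (6 + 6 * 2^level)` = 102 columns
#' per channel at level 4, i.e. 1836 for an 18-channel set and 1326 for a
#' 13-channel set.
#'
#' @param time_block,wpd_block matrices from [extract_time_features()] and
#'   [extract_wpd_features()] (either may be `NULL` or zero-column).
#' @param labels per-trial class labels.
#' @return an [mi_features()] object.
#' @export
fuse_features <- function(time_block, wpd_block, labels) {
  pieces <- Filter(function(b) !is.null(b) && ncol(b) > 0L,
                   list(time_block, wpd_block))
  if (!length(pieces)) stop_mibci("empty_input", "both feature blocks are empty")
  n <- unique(vapply(pieces, nrow, integer(1)))
  if (length(n) != 1L)
    stop_mibci("alignment", "trial count mismatch between feature blocks")
  mi_features(do.call(cbind, pieces), labels)
}
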