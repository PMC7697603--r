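# Periodized orthogonal wavelet packet transform.
#
# The analysis step computes a[k] = sum_n h[n] x[(2k + n) mod M] (and the
# same with the quadrature mirror g), which is an orthogonal M x M operator:
# energy is conserved exactly and the synthesis step is its transpose, so
# reconstruction is exact to round-off.  Both the approximation and detail
# branches are split recursively; the 2^level terminal nodes are returned in
# frequency-ascending order (binary-reflected Gray-code reordering of the
# natural tree order, which undoes the band reversal that decimating a
# high-pass branch introduces).

# Daubechies low-pass decomposition filters (orthonormal, sum = sqrt(2)).
.db_filters <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255126037, 0.2241438680420134,
          0.8365163037378079, 0.48296291314453416),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  db8 = c(-0.00011747678412476953, 0.0006754494064505693, -0.00039174037337694705,
          -0.004870352993451574, 0.008746094047405777, 0.013981027917398282,
          -0.044088253930794755, -0.017369301001807547, 0.12874742662047847,
          0.0004724845739132828, -0.2840155429615469, -0.015829105256349306,
          0.5853546836542067, 0.6756307362972898, 0.31287159091429995,
          0.05441584224310401)
)

#' Decomposition filter pair of an orthogonal wavelet family
#'
#' @param wavelet family name: one of `"db1"` (Haar), `"db2"`, `"db4"`,
#'   `"db8"`.
#' @return list with low-pass `h` and high-pass `g` decomposition filters.
#' @export
wavelet_filter <- function(wavelet = "db4") {
  h <- .db_filters[[wavelet]]
  if (is.null(h))
    stop_mibci("parameter", "unknown wavelet '%s' (available: %s)", wavelet,
               paste(names(.db_filters), collapse = ", "))
  n <- seq_along(h) - 1L
  g <- rev(h) * (-1)^(n + 1)   # quadrature mirror, PyWavelets sign convention
  list(h = h, g = g)
}

# one periodized analysis step on the rows of matrix X (n x M), M even
.wpd_step <- function(X, f) {
  M <- ncol(X); K <- M %/% 2L; L <- length(f)
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    cols <- ((2L * (k - 1L) + seq_len(L) - 1L) %% M) + 1L
    out[, k] <- X[, cols, drop = FALSE] %*% f
  }
  out
}

# periodized synthesis (transpose of the analysis operator)
.wpd_unstep <- function(A, D, f) {
  h <- f$h; g <- f$g; L <- length(h)
  K <- ncol(A); M <- 2L * K
  out <- matrix(0, nrow(A), M)
  for (k in seq_len(K)) {
    cols <- (((2L * (k - 1L)) + seq_len(L) - 1L) %% M) + 1L
    out[, cols] <- out[, cols] + outer(A[, k], h) + outer(D[, k], g)
  }
  out
}

# full packet tree on rows of X; returns list of 2^level matrices in
# natural (tree) order, plus the per-node original lengths for inversion
.wpd_tree <- function(X, level, f) {
  nodes <- list(X)
  pads <- list()
  for (l in seq_len(level)) {
    nxt <- vector("list", 2L * length(nodes))
    pad <- logical(length(nodes))
    for (i in seq_along(nodes)) {
      nd <- nodes[[i]]
      if (ncol(nd) %% 2L) {       # odd node length: one zero-pad column
        nd <- cbind(nd, 0)
        pad[i] <- TRUE
      }
      if (ncol(nd) < length(f$h))
        stop_mibci("decomposition_depth",
                   "signal too short for a level-%d decomposition", level)
      nxt[[2L * i - 1L]] <- .wpd_step(nd, f$h)
      nxt[[2L * i]] <- .wpd_step(nd, f$g)
    }
    nodes <- nxt
    pads[[l]] <- pad
  }
  list(nodes = nodes, pads = pads)
}

.gray <- function(n) bitwXor(n, bitwShiftR(n, 1L))

#' Wavelet packet decomposition of a signal
#'
#' Decomposes `y` with a `level`-deep wavelet packet tree under periodic
#' extension and returns the `2^level` terminal coefficient vectors in
#' frequency-ascending order.  For signal lengths divisible by `2^level`
#' the transform is orthogonal: the coefficient count equals the signal
#' length and total energy is conserved exactly (other lengths are
#' zero-padded per stage, which preserves energy but can add a few
#' coefficients).
#'
#' @param y numeric vector (length >= filter length).
#' @param level decomposition depth (default 4, giving 16 sub-bands).
#' @param wavelet wavelet family (see [wavelet_filter()]).
#' @return object of class `wpd_nodes`: list with `nodes` (list of numeric
#'   vectors, frequency-ascending), `level`, `wavelet`, `ordering`, and the
#'   internal padding bookkeeping used by [wpd_reconstruct()].
#' @export
wpd_decompose <- function(y, level = 4L, wavelet = "db4") {
  if (!is_count(level)) stop_mibci("parameter", "level must be >= 1")
  f <- wavelet_filter(wavelet)
  if (length(y) < length(f$h))
    stop_mibci("decomposition_depth", "signal shorter than the wavelet filter")
  tr <- .wpd_tree(matrix(y, nrow = 1L), level, f)
  natural <- lapply(tr$nodes, function(m) m[1L, ])
  perm <- .gray(seq_len(2^level) - 1L) + 1L   # freq position -> natural index
  structure(list(nodes = natural[perm], level = level, wavelet = wavelet,
                 ordering = "frequency-ascending",
                 n = length(y), pads = tr$pads),
            class = "wpd_nodes")
}

#' @export
print.wpd_nodes <- function(x, ...) {
  cat(sprintf("<wpd_nodes> level %d (%s), %d sub-bands of %s coefficients, %s\n",
              x$level, x$wavelet, length(x$nodes),
              paste(unique(lengths(x$nodes)), collapse = "/"), x$ordering))
  invisible(x)
}

#' Inverse wavelet packet transform
#'
#' Reconstructs the original signal from a [wpd_decompose()] result by
#' applying the transposed analysis operator level by level; exact to
#' numerical round-off.
#'
#' @param nodes a `wpd_nodes` object.
#' @return numeric vector of the original signal length.
#' @export
wpd_reconstruct <- function(nodes) {
  stopifnot(inherits(nodes, "wpd_nodes"))
  f <- wavelet_filter(nodes$wavelet)
  perm <- .gray(seq_len(2^nodes$level) - 1L) + 1L
  natural <- vector("list", 2^nodes$level)
  natural[perm] <- nodes$nodes
  mats <- lapply(natural, function(v) matrix(v, nrow = 1L))
  for (l in rev(seq_len(nodes$level))) {
    pad <- nodes$pads[[l]]
    up <- vector("list", length(mats) / 2L)
    for (i in seq_along(up)) {
      m <- .wpd_unstep(mats[[2L * i - 1L]], mats[[2L * i]], f)
      if (pad[i]) m <- m[, -ncol(m), drop = FALSE]
      up[[i]] <- m
    }
    mats <- up
  }
  mats[[1L]][1L, ]
}

# matrix variant used by the feature extractor: decompose all trials of one
# channel at once; returns list of 2^level matrices (trials x coefficients),
# frequency-ascending
.wpd_decompose_rows <- function(X, level, f) {
  tr <- .wpd_tree(X, level, f)
  perm <- .gray(seq_len(2^level) - 1L) + 1L
  tr$nodes[perm]
}
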