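# Independent oracles and fixture builders used across the suite.

tmpfile_with <- function(lines) {
  p <- tempfile()
  writeLines(lines, p)
  p
}

# tiny contact map from a triplet matrix
cm_from_triplets <- function(trip, n_bins = "infer", resolution = 10000L) {
  contact_map(i = trip[, 1], j = trip[, 2], value = trip[, 3],
              n_bins = n_bins, resolution = resolution)
}

random_sparse_cm <- function(n_bins, n_rec, seed) {
  set.seed(seed)
  i <- sample.int(n_bins, n_rec, replace = TRUE) - 1L
  j <- sample.int(n_bins, n_rec, replace = TRUE) - 1L
  v <- stats::rexp(n_rec, rate = 0.2)
  suppressWarnings(contact_map(i = i, j = j, value = v, n_bins = n_bins))
}

# brute-force sliding-window smoother: forward window, tail truncated to
# >= min_window points, extending backward at the very end
smooth_oracle <- function(E, window = 10L, min_window = 5L) {
  M <- length(E)
  vapply(seq_len(M), function(i) {
    avail <- M - i + 1L
    if (avail >= window) mean(E[i:(i + window - 1L)])
    else if (avail >= min_window) mean(E[i:M])
    else mean(E[(M - min_window + 1L):M])
  }, numeric(1))
}

# two-sided Fisher p by direct hypergeometric enumeration (dhyper route,
# independent of the package's lchoose implementation)
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  x <- max(0, c1 - r2):min(r1, c1)
  dh <- stats::dhyper(x, r1, r2, c1)
  sum(dh[dh <= dh[x == a] * (1 + 1e-7)])
}

# rigid Procrustes (rotation/reflection + translation, no scaling) RMSD
procrustes_rmsd <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Xc, Yc))
  R <- s$u %*% t(s$v)
  sqrt(mean(rowSums((Xc %*% R - Yc)^2)))
}

# random planar point configuration and its exact Euclidean distance matrix
planar_config <- function(n, seed) {
  set.seed(seed)
  cbind(stats::runif(n, -3, 3), stats::runif(n, -3, 3))
}
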