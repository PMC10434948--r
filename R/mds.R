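#' Torgerson double centering
#'
#' Converts a squared distance matrix into the centered inner-product (Gram)
#' matrix of classical MDS: `K = -1/2 * J D^(2) J` with centering matrix
#' `J = I - (1/n) 11'`. Every row and column of `K` sums to zero.
#'
#' @param dm Square symmetric distance matrix with zero diagonal.
#' @return The symmetric Gram matrix `K`.
#' @export
double_center <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 2L || ncol(dm) != n) stop("'dm' must be square with n >= 2")
  D2 <- dm * dm
  rm <- rowMeans(D2)
  K <- -0.5 * (D2 - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(D2))
  (K + t(K)) / 2
}

#' Classical MDS embedding of a distance matrix
#'
#' Eigendecomposes the double-centered Gram matrix and returns the
#' eigenvectors of the requested ranks (sorted by algebraically descending
#' eigenvalue) as per-bin planar coordinates. The default selects ranks 2 and
#' 3 — empirically the components that retain the chromosome's spatial
#' structure for these distance matrices — as raw unit-norm eigenvectors.
#' `scale_eigen = TRUE` instead scales each column by the square root of its
#' (non-negative part of the) eigenvalue, the textbook Torgerson coordinates
#' that exactly reproduce Euclidean distance matrices from ranks 1 and 2.
#'
#' Negative eigenvalues (non-Euclidean input) are retained in the spectrum for
#' diagnostics but are never selected by the default ranks.
#'
#' @param dm Square symmetric distance matrix, zero diagonal.
#' @param components Integer pair of eigenvector ranks (1-based, by
#'   descending eigenvalue).
#' @param scale_eigen Scale columns by `sqrt(max(lambda, 0))`?
#' @return An object of class `mds_embedding`: list with `coords`
#'   (`n x length(components)` matrix), `eigenvalues` (full spectrum,
#'   non-increasing), `components`, `scaled`.
#' @export
mds_embed <- function(dm, components = c(2, 3), scale_eigen = FALSE) {
  K <- double_center(dm)
  n <- nrow(K)
  components <- as.integer(components)
  if (any(components < 1L) || any(components > n))
    stop("requested component rank outside 1..", n)
  e <- eigen(K, symmetric = TRUE)   # values already non-increasing
  coords <- e$vectors[, components, drop = FALSE]
  if (scale_eigen)
    coords <- sweep(coords, 2, sqrt(pmax(e$values[components], 0)), `*`)
  structure(
    list(coords = coords, eigenvalues = e$values,
         components = components, scaled = isTRUE(scale_eigen)),
    class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("mds_embedding: %d bins, components (%s)%s\n",
              nrow(x$coords), paste(x$components, collapse = ", "),
              if (x$scaled) ", sqrt(eigenvalue)-scaled" else ""))
  ev <- x$eigenvalues
  cat(sprintf("  leading eigenvalues: %s\n",
              paste(signif(utils::head(ev, 5), 4), collapse = ", ")))
  invisible(x)
}
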