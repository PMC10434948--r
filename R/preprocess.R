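#' Distance-dependent contact weighting
#'
#' Contact frequencies between distant loci that form loops are systematically
#' underestimated relative to short-range contacts, so contacts beyond a
#' genomic-distance cutoff are amplified before embedding. In `"log"` mode
#' (the default used throughout),
#' \deqn{d'_{ij} = d_{ij} \ln|i-j| \quad \mathrm{for} \quad |i-j| > c,}
#' and `d'_ij = d_ij` within the cutoff band. `"const"` mode instead uses a
#' linear ramp `d_ij * a * |i-j|` beyond the cutoff (kept for comparison; it
#' does not reproduce loop-consistent structures).
#'
#' The default cutoff is 50 kbp expressed in bins
#' (`ceiling(50000 / resolution)`, i.e. 5 bins at 10 kb resolution), below
#' which raw short-range contacts are left untouched.
#'
#' @param cm A `contact_map` (normally VC-normalized).
#' @param mode `"log"` or `"const"`.
#' @param cutoff_bins Band half-width in bins; contacts with
#'   `|i - j| <= cutoff_bins` are unweighted.
#' @param a Positive constant for `"const"` mode.
#' @return A `contact_map`-shaped object of class `c("weighted_map",
#'   "contact_map")` with weighted values.
#' @export
weight_contacts <- function(cm, mode = c("log", "const"),
                            cutoff_bins = NULL, a = NULL) {
  stopifnot(inherits(cm, "contact_map"))
  mode <- match.arg(mode)
  if (is.null(cutoff_bins)) cutoff_bins <- ceiling(50000 / cm$resolution)
  cutoff_bins <- as.integer(cutoff_bins)
  if (cutoff_bins < 1L) stop("'cutoff_bins' must be >= 1")
  if (mode == "const" && (is.null(a) || a <= 0))
    stop("'const' mode requires a > 0")
  r <- cm$records
  sep <- abs(r$j - r$i)
  far <- sep > cutoff_bins
  stopifnot(all(sep[far] >= 2L))  # ln 1 = 0 cannot occur with cutoff >= 1
  v <- r$value
  if (mode == "log") {
    v[far] <- v[far] * log(sep[far])
  } else {
    v[far] <- v[far] * a * sep[far]
  }
  cm$records$value <- v
  cm$weight <- list(mode = mode, cutoff_bins = cutoff_bins, a = a)
  class(cm) <- c("weighted_map", "contact_map")
  cm
}

#' Contact-to-distance transformation
#'
#' Large weighted contacts mean spatial proximity, so the reciprocal is used
#' as the distance fed to multidimensional scaling:
#' \deqn{D_{ij} = 1 / (d'_{ij} + 1), \quad D_{ii} = 0.}
#' The `+1` accommodates missing contacts (treated as zero), which map to the
#' maximal distance 1; off-diagonal entries always lie in `(0, 1]` and
#' decrease monotonically with contact strength.
#'
#' @param wm A `weighted_map` (or plain `contact_map`).
#' @param n_bins Matrix order; defaults to `wm$n_bins`.
#' @return A dense symmetric `n_bins x n_bins` numeric matrix.
#' @export
to_distance_matrix <- function(wm, n_bins = NULL) {
  stopifnot(inherits(wm, "contact_map"))
  if (is.null(n_bins)) n_bins <- wm$n_bins
  if (n_bins < 2L) stop("'n_bins' must be >= 2")
  D <- matrix(1, n_bins, n_bins)
  r <- wm$records
  if (nrow(r)) {
    d <- 1 / (r$value + 1)
    D[cbind(r$i + 1L, r$j + 1L)] <- d
    D[cbind(r$j + 1L, r$i + 1L)] <- d
  }
  diag(D) <- 0
  D
}
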