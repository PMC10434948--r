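#' Specification of a synthetic looped-chromosome contact map
#'
#' Ground-truth generator settings: a planar Gaussian random-walk backbone
#' with planted loops (Brownian bridges whose two anchors coincide), contacts
#' drawn with inverse-power distance decay, Poisson counting noise at a fixed
#' sequencing depth and uniform entry dropout emulating missing values.
#'
#' @param n_bins Number of bins.
#' @param loops List of `c(anchor_left, anchor_right)` 0-based bin pairs;
#'   must be disjoint, non-nested and satisfy `anchor_left + 2 < anchor_right`.
#' @param step_sd Random-walk step standard deviation per coordinate
#'   (arbitrary spatial units; the contact model is scale-free in it).
#' @param alpha Distance-decay exponent, `lambda ~ 1/(eps + dist)^alpha`;
#'   1 as in fractal-globule contact scaling.
#' @param depth Expected total contact count over the map.
#' @param dropout Fraction of nonzero entries deleted at random, in `[0, 1)`.
#' @param seed Integer seed; all randomness flows from it.
#' @param dims Spatial dimension of the walk (2 matches the planar embedding;
#'   3 available for robustness checks).
#' @param short_range_boost Multiplier applied to `|i - j| <= 1` intensities,
#'   emulating the short-range excess of raw Hi-C maps.
#' @param resolution,chrom Metadata for the generated `contact_map`.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_bins = 500L, loops = list(c(100L, 150L),
                                                       c(300L, 380L)),
                           step_sd = 1, alpha = 1, depth = 1e5, dropout = 0.3,
                           seed = 1L, dims = 2L, short_range_boost = 10,
                           resolution = 10000L, chrom = "chrS") {
  stopifnot(n_bins >= 10L, step_sd > 0, alpha > 0, depth > 0,
            dropout >= 0, dropout < 1, dims %in% c(2L, 3L),
            short_range_boost >= 1)
  if (length(loops)) {
    anc <- do.call(rbind, lapply(loops, as.integer))
    if (any(anc[, 1] < 0L) || any(anc[, 2] >= n_bins) ||
        any(anc[, 1] + 2L >= anc[, 2]))
      stop("infeasible loop anchors")
    anc <- anc[order(anc[, 1]), , drop = FALSE]
    if (nrow(anc) > 1L && any(anc[-1L, 1] <= anc[-nrow(anc), 2]))
      stop("loop anchors must be disjoint and non-nested")
    loops <- lapply(seq_len(nrow(anc)), function(k) anc[k, ])
  }
  structure(list(n_bins = as.integer(n_bins), loops = loops,
                 step_sd = step_sd, alpha = alpha, depth = depth,
                 dropout = dropout, seed = as.integer(seed),
                 dims = as.integer(dims), short_range_boost = short_range_boost,
                 resolution = as.integer(resolution), chrom = chrom),
            class = "synthetic_spec")
}

#' Simulate a looped-polymer backbone
#'
#' Seeded Gaussian random walk with step sd `step_sd` per coordinate. For
#' each planted loop the walk between the two anchors is replaced by a
#' Brownian bridge conditioned so the anchors coincide to within
#' `step_sd / 2` (offset drawn with sd `step_sd / 10`); the walk after the
#' loop continues from the bridged anchor, so increments outside loops are
#' untouched.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `coords` (`n_bins x dims` matrix) and `truth` (a
#'   [loop_set()] of the planted anchor intervals).
#' @export
simulate_structure <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_bins; d <- spec$dims; s <- spec$step_sd
  steps <- matrix(stats::rnorm((n - 1L) * d, 0, s), n - 1L, d)
  coords <- apply(rbind(0, steps), 2, cumsum)
  for (lp in spec$loops) {
    a <- lp[1] + 1L; b <- lp[2] + 1L        # 1-based anchor rows
    L <- b - a
    repeat {
      delta <- stats::rnorm(d, 0, s / 10)
      if (sqrt(sum(delta^2)) < s / 2) break
    }
    seg <- sweep(coords[a:b, , drop = FALSE], 2, coords[a, ], `-`)
    endgap <- seg[L + 1L, ] - delta          # bridge: remove linear drift
    t_frac <- (0:L) / L
    bridged <- seg - outer(t_frac, endgap)
    shift <- (coords[a, ] + bridged[L + 1L, ]) - coords[b, ]
    coords[a:b, ] <- sweep(bridged, 2, coords[a, ], `+`)
    if (b < n)
      coords[(b + 1L):n, ] <- sweep(coords[(b + 1L):n, , drop = FALSE],
                                    2, shift, `+`)
  }
  truth <- loop_set(
    data.frame(left_root = vapply(spec$loops, `[`, 1L, FUN.VALUE = 1L),
               right_root = vapply(spec$loops, `[`, 2L, FUN.VALUE = 1L)),
    chrom = spec$chrom, resolution = spec$resolution, n_bins = n)
  list(coords = coords, truth = truth)
}

#' Draw a contact map from a spatial structure
#'
#' Expected contact intensity `lambda_ij ~ 1/(eps + |x_i - x_j|)^alpha` with
#' `eps = step_sd / 10` regularizing coincident points, short-range
#' (`|i - j| <= 1`) intensities multiplied by `short_range_boost`, the whole
#' intensity field normalized to the requested sequencing depth. Observed
#' counts are Poisson; a `dropout` fraction of the nonzero entries is then
#' deleted uniformly at random. Uses its own RNG stream at `seed + 1` so the
#' counts are reproducible whether or not the structure was just simulated.
#'
#' @param coords Coordinate matrix from [simulate_structure()].
#' @param spec The same [synthetic_spec()].
#' @return A raw [contact_map()].
#' @export
structure_to_contacts <- function(coords, spec) {
  stopifnot(inherits(spec, "synthetic_spec"), nrow(coords) == spec$n_bins)
  set.seed(spec$seed + 1L)
  n <- spec$n_bins
  eps <- spec$step_sd / 10
  dmat <- as.matrix(stats::dist(coords))
  ut <- which(upper.tri(dmat, diag = TRUE), arr.ind = TRUE)
  lam <- 1 / (eps + dmat[ut])^spec$alpha
  near <- abs(ut[, 2] - ut[, 1]) <= 1L
  lam[near] <- lam[near] * spec$short_range_boost
  lam <- lam * spec$depth / sum(lam)
  counts <- stats::rpois(length(lam), lam)
  nz <- counts > 0L
  i <- ut[nz, 1] - 1L; j <- ut[nz, 2] - 1L; v <- counts[nz]
  if (spec$dropout > 0 && length(v)) {
    keep <- stats::runif(length(v)) >= spec$dropout
    i <- i[keep]; j <- j[keep]; v <- v[keep]
  }
  contact_map(i = i, j = j, value = v, n_bins = n,
              resolution = spec$resolution, chrom = spec$chrom)
}

#' Simulate a complete synthetic Hi-C dataset
#'
#' Convenience wrapper: [simulate_structure()] then
#' [structure_to_contacts()].
#'
#' @param spec A [synthetic_spec()].
#' @return List with `contacts` (raw `contact_map`), `coords`, `truth`.
#' @export
simulate_hic <- function(spec) {
  st <- simulate_structure(spec)
  list(contacts = structure_to_contacts(st$coords, spec),
       coords = st$coords, truth = st$truth)
}
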