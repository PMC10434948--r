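#' Consecutive-bin step distances
#'
#' Euclidean distance between each pair of consecutive embedded bins,
#' `E_i = || coords[i + 1, ] - coords[i, ] ||`. Bins inside loop excursions
#' travel farther per step in the planar embedding, so large values of `E`
#' mark candidate loops.
#'
#' @param emb An `mds_embedding` or a numeric coordinate matrix.
#' @return Numeric vector of length `n - 1`; element `i` (1-based) is the
#'   step from bin `i - 1` to bin `i` (0-based bins).
#' @export
step_distances <- function(emb) {
  coords <- if (inherits(emb, "mds_embedding")) emb$coords else as.matrix(emb)
  if (nrow(coords) < 2L) stop("need at least 2 embedded bins")
  d <- diff(coords)
  sqrt(rowSums(d * d))
}

#' Boundary-corrected running-mean smoothing of a step profile
#'
#' Interior positions take the forward mean of `window` consecutive values
#' (10 steps = 100 kbp at 10 kb resolution, commensurate with typical loop
#' lengths). Near the right boundary, where fewer than `window` forward values
#' remain, the window is truncated to the available points but never below
#' `min_window`; the last positions extend backward so that at least
#' `min_window` points are always averaged.
#'
#' @param E Raw step-distance vector.
#' @param window Full window length in steps.
#' @param min_window Minimum window length at the boundary.
#' @return Smoothed vector `E'` of the same length as `E`.
#' @export
smooth_profile <- function(E, window = 10L, min_window = 5L) {
  window <- as.integer(window); min_window <- as.integer(min_window)
  if (window < 1L || min_window < 1L || min_window > window)
    stop("need 1 <= min_window <= window")
  M <- length(E)
  if (M == 0L) stop("'E' is empty")
  if (M < window) {
    warning("profile shorter than the smoothing window; global mean used")
    return(rep(mean(E), M))
  }
  cs <- c(0, cumsum(E))
  out <- numeric(M)
  n_full <- M - window + 1L
  ii <- seq_len(n_full)
  out[ii] <- (cs[ii + window] - cs[ii]) / window
  if (n_full < M) {
    for (i in (n_full + 1L):M) {
      k <- M - i + 1L                       # forward points available
      out[i] <- if (k >= min_window) (cs[M + 1L] - cs[i]) / k
                else (cs[M + 1L] - cs[M - min_window + 1L]) / min_window
    }
  }
  out
}

#' Called DNA-loop regions
#'
#' Container for loop regions on one chromosome. Each region runs from its
#' left root bin to its right root bin (inclusive, 0-based); roots are the
#' flanking local minima of the smoothed step profile and are interpreted as
#' the loop anchors (enhancer/promoter candidates).
#'
#' @param loops data.frame with integer columns `left_root`, `right_root` and
#'   a list column `above_bins` of the above-threshold bins in each region.
#' @param chrom Chromosome label.
#' @param resolution Bin width in bp.
#' @param n_bins Total bins in the analyzed segment(s) (for coverage
#'   bookkeeping); may be `NA`.
#' @param threshold Calling threshold `T` (may be `NA` for e.g. planted truth).
#' @return An object of class `loop_set`.
#' @export
loop_set <- function(loops = data.frame(left_root = integer(),
                                        right_root = integer()),
                     chrom = "chr1", resolution = 10000L, n_bins = NA_integer_,
                     threshold = NA_real_) {
  if (is.null(loops$above_bins)) loops$above_bins <- vector("list", nrow(loops))
  stopifnot(all(loops$left_root < loops$right_root))
  if (nrow(loops) > 1L) {
    ord <- order(loops$left_root)
    loops <- loops[ord, , drop = FALSE]
    if (any(loops$left_root[-1L] <= loops$right_root[-nrow(loops)]))
      stop("loop regions must be pairwise non-overlapping")
  }
  rownames(loops) <- NULL
  structure(list(loops = loops, chrom = chrom,
                 resolution = as.integer(resolution),
                 n_bins = n_bins, threshold = threshold),
            class = "loop_set")
}

#' @export
print.loop_set <- function(x, ...) {
  cat(sprintf("loop_set: %d region(s) on %s @ %d bp\n",
              nrow(x$loops), x$chrom, x$resolution))
  if (!is.na(x$n_bins)) {
    fr <- loop_fraction(x)
    cat(sprintf("  bins in loops: %d/%d = %s\n",
                fr$numerator, fr$denominator, fr$formatted))
  }
  invisible(x)
}

#' @method as.data.frame loop_set
#' @export
as.data.frame.loop_set <- function(x, ...) {
  data.frame(left_root = x$loops$left_root, right_root = x$loops$right_root)
}

#' Genomic bp intervals of loop regions
#'
#' @param loops A `loop_set`.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open bp), one row
#'   per region, sorted by start.
#' @export
loop_intervals <- function(loops) {
  stopifnot(inherits(loops, "loop_set"))
  l <- loops$loops
  data.frame(chrom = rep(loops$chrom, nrow(l)),
             start = l$left_root * loops$resolution,
             end = (l$right_root + 1L) * loops$resolution)
}

#' Call loop regions from a smoothed step profile
#'
#' The calling threshold is `T = factor * mean(E_smooth)` (twice the average
#' step distance by default). Each maximal run of positions with
#' `E_smooth > T` forms a loop core. From both ends of a core the profile is
#' walked outward through sub-threshold positions while values strictly
#' decrease; the walk stops at the first local minimum, whose position becomes
#' the loop root (the loop end/anchor). Walks also stop at the profile
#' boundaries and, between two adjacent cores, at the midpoint of the gap so
#' regions never overlap; regions that come to share a root are merged.
#'
#' Profile position `i` (1-based in R) is reported as 0-based bin `i - 1`.
#'
#' @param E_smooth Smoothed step profile.
#' @param factor Threshold multiple of the mean (default 2).
#' @param chrom,resolution Genomic metadata for the output.
#' @param offset Integer added to all bin indices (segment start bin).
#' @param threshold Explicit threshold `T` overriding `factor * mean` (used
#'   e.g. when the mean is taken over the raw rather than smoothed profile).
#' @return A [loop_set()]; empty when nothing exceeds the threshold.
#' @export
call_loops <- function(E_smooth, factor = 2, chrom = "chr1",
                       resolution = 10000L, offset = 0L, threshold = NULL) {
  M <- length(E_smooth)
  if (M == 0L) stop("'E_smooth' is empty")
  thr <- if (is.null(threshold)) factor * mean(E_smooth) else threshold
  above <- E_smooth > thr
  empty <- loop_set(chrom = chrom, resolution = resolution,
                    n_bins = M, threshold = thr)
  if (!any(above)) return(empty)

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cs <- starts[r$values]; ce <- ends[r$values]   # cores, 1-based
  ncore <- length(cs)

  # walk outward from 'from' while strictly decreasing, capped at 'cap'
  walk <- function(from, cap, dir) {
    p <- from
    repeat {
      nxt <- p + dir
      if ((dir < 0L && nxt < cap) || (dir > 0L && nxt > cap)) break
      if (E_smooth[nxt] < E_smooth[p]) p <- nxt else break
    }
    p
  }

  lroot <- rroot <- integer(ncore)
  for (k in seq_len(ncore)) {
    lcap <- if (k == 1L) 1L else ceiling((ce[k - 1L] + cs[k]) / 2)
    rcap <- if (k == ncore) M else floor((ce[k] + cs[k + 1L]) / 2)
    lroot[k] <- walk(cs[k], lcap, -1L)
    rroot[k] <- walk(ce[k], rcap, +1L)
  }

  # merge regions sharing a root (adjacent cores meeting at the gap midpoint)
  regions <- data.frame(l = lroot, r = rroot)
  above_list <- lapply(seq_len(ncore), function(k) cs[k]:ce[k])
  k <- 1L
  while (k < nrow(regions)) {
    if (regions$r[k] >= regions$l[k + 1L]) {
      regions$r[k] <- regions$r[k + 1L]
      above_list[[k]] <- c(above_list[[k]], above_list[[k + 1L]])
      regions <- regions[-(k + 1L), , drop = FALSE]
      above_list <- above_list[-(k + 1L)]
    } else k <- k + 1L
  }

  loops <- data.frame(left_root = regions$l - 1L + offset,
                      right_root = regions$r - 1L + offset)
  loops$above_bins <- lapply(above_list, function(b) b - 1L + offset)
  loop_set(loops, chrom = chrom, resolution = resolution,
           n_bins = M, threshold = thr)
}

#' Loop coverage bookkeeping
#'
#' Exact fraction of bins lying inside loop regions (roots included), the
#' summary arithmetic reported per dataset: `bins in loops / total bins`.
#'
#' @param loops A `loop_set`.
#' @param total_bins Denominator; defaults to `loops$n_bins`.
#' @return A [report_fraction()] list.
#' @export
loop_fraction <- function(loops, total_bins = NULL) {
  stopifnot(inherits(loops, "loop_set"))
  if (is.null(total_bins)) total_bins <- loops$n_bins
  inside <- sum(loops$loops$right_root - loops$loops$left_root + 1L)
  report_fraction(inside, total_bins)
}

#' Exact fraction reporting
#'
#' Reports `numerator / denominator` both exactly and rounded to 3 decimal
#' places, the format used in the per-dataset summary tables (e.g.
#' `31860/318380 = 0.100`).
#'
#' @param numerator,denominator Non-negative numbers, `denominator > 0`.
#' @param digits Decimal places for the formatted value.
#' @return List with `numerator`, `denominator`, `fraction` and a `formatted`
#'   string.
#' @export
report_fraction <- function(numerator, denominator, digits = 3L) {
  if (denominator <= 0) stop("'denominator' must be positive")
  structure(list(numerator = numerator, denominator = denominator,
                 fraction = numerator / denominator,
                 formatted = formatC(round(numerator / denominator, digits),
                                     format = "f", digits = digits)),
            class = "fraction_report")
}

#' @export
print.fraction_report <- function(x, ...) {
  cat(sprintf("%s/%s = %s\n", format(x$numerator, scientific = FALSE),
              format(x$denominator, scientific = FALSE), x$formatted))
  invisible(x)
}

#' Recovery of planted loops by called regions
#'
#' For each true (planted) loop, the best Jaccard index between its bin
#' interval and any called region; a loop counts as recovered when that
#' Jaccard is at least `min_jaccard`.
#'
#' @param called,truth `loop_set` objects on the same bin grid.
#' @param min_jaccard Recovery threshold on the Jaccard index.
#' @return List with `jaccard` (per true loop), `recovered` (logical),
#'   `recall`.
#' @export
loop_recovery <- function(called, truth, min_jaccard = 0.5) {
  stopifnot(inherits(called, "loop_set"), inherits(truth, "loop_set"))
  tl <- truth$loops; cl <- called$loops
  jac <- vapply(seq_len(nrow(tl)), function(k) {
    a1 <- tl$left_root[k]; a2 <- tl$right_root[k]
    if (!nrow(cl)) return(0)
    inter <- pmax(0L, pmin(a2, cl$right_root) - pmax(a1, cl$left_root) + 1L)
    un <- (a2 - a1 + 1L) + (cl$right_root - cl$left_root + 1L) - inter
    max(inter / un)
  }, numeric(1))
  list(jaccard = jac, recovered = jac >= min_jaccard,
       recall = if (length(jac)) mean(jac >= min_jaccard) else NA_real_)
}
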