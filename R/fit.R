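#' Fit the MDS loop-calling model to a contact map
#'
#' The full estimator: vanilla-coverage normalization (unless the map is
#' already normalized), distance-decay weighting, inverse-contact distance
#' transform, classical MDS embedding per chromosome segment, consecutive-bin
#' step distances, boundary-corrected running-mean smoothing, and threshold
#' loop calling. Long chromosomes are processed in independent windows of
#' `window_bins` bins (dense eigendecomposition per window) and the loop
#' calls concatenated.
#'
#' @param contacts A [contact_map()] or a path passed to [read_contacts()].
#' @param weight_mode `"log"` (default) or `"const"` (see
#'   [weight_contacts()]).
#' @param cutoff_bins Unweighted band half-width in bins; default
#'   `ceiling(50000 / resolution)`.
#' @param const_a Constant for `weight_mode = "const"`.
#' @param components Eigenvector ranks used as coordinates (default `c(2, 3)`).
#' @param scale_eigen Use `sqrt(eigenvalue)`-scaled coordinates instead of raw
#'   unit eigenvectors.
#' @param window_bins Segment length in bins (default 5000, i.e. 50 Mb at
#'   10 kb).
#' @param smooth_window,min_window Smoothing parameters, see
#'   [smooth_profile()].
#' @param threshold_factor Threshold multiple of the mean step distance
#'   (default 2).
#' @param threshold_on Take the mean defining the threshold over the
#'   `"smooth"`ed (default) or `"raw"` profile.
#' @param normalize Apply [vc_normalize()] to raw input?
#' @param resolution,chrom,n_bins Passed to [read_contacts()] when `contacts`
#'   is a path.
#' @return An object of class `mds_loops`: list with `loops` (a
#'   [loop_set()]), `profile` (data.frame `bin`, `segment`, `E`, `E_smooth`,
#'   `threshold`, `above`), `segments` (per-segment embeddings), `params`,
#'   `chrom`, `resolution`, `n_bins`, `call`.
#' @examples
#' sim <- simulate_hic(synthetic_spec(seed = 7))
#' fit <- mds_loops(sim$contacts)
#' print(fit)
#' loop_recovery(fit$loops, sim$truth)$jaccard
#' @export
mds_loops <- function(contacts, weight_mode = c("log", "const"),
                      cutoff_bins = NULL, const_a = NULL,
                      components = c(2, 3), scale_eigen = FALSE,
                      window_bins = 5000L, smooth_window = 10L,
                      min_window = 5L, threshold_factor = 2,
                      threshold_on = c("smooth", "raw"), normalize = TRUE,
                      resolution = 10000L, chrom = "chr1", n_bins = "infer") {
  cl <- match.call()
  weight_mode <- match.arg(weight_mode)
  threshold_on <- match.arg(threshold_on)
  if (is.character(contacts))
    contacts <- read_contacts(contacts, resolution = resolution,
                              chrom = chrom, n_bins = n_bins)
  stopifnot(inherits(contacts, "contact_map"))
  if (normalize && !contacts$normalized) contacts <- vc_normalize(contacts)

  n <- contacts$n_bins
  seg_starts <- seq(0L, n - 1L, by = window_bins)
  # avoid a stub final segment: fold a tail shorter than half a window into
  # the previous segment
  if (length(seg_starts) > 1L && n - seg_starts[length(seg_starts)] < window_bins / 2)
    seg_starts <- seg_starts[-length(seg_starts)]

  segments <- vector("list", length(seg_starts))
  all_loops <- list(); prof <- list()
  for (s in seq_along(seg_starts)) {
    from <- seg_starts[s]
    to <- if (s < length(seg_starts)) seg_starts[s + 1L] - 1L else n - 1L
    sub <- slice_contacts(contacts, from, to)
    wm <- weight_contacts(sub, mode = weight_mode,
                          cutoff_bins = cutoff_bins, a = const_a)
    D <- to_distance_matrix(wm)
    emb <- mds_embed(D, components = components, scale_eigen = scale_eigen)
    E <- step_distances(emb)
    Es <- smooth_profile(E, window = smooth_window, min_window = min_window)
    base <- if (threshold_on == "smooth") Es else E
    thr <- threshold_factor * mean(base)
    ls <- call_loops(Es, threshold = thr,
                     chrom = contacts$chrom, resolution = contacts$resolution,
                     offset = from)
    segments[[s]] <- list(from = from, to = to, embedding = emb,
                          threshold = thr)
    all_loops[[s]] <- ls$loops
    prof[[s]] <- data.frame(bin = from + seq_along(E) - 1L, segment = s,
                            E = E, E_smooth = Es, threshold = thr,
                            above = Es > thr)
  }
  loops <- loop_set(do.call(rbind, all_loops), chrom = contacts$chrom,
                    resolution = contacts$resolution, n_bins = n,
                    threshold = segments[[1L]]$threshold)
  structure(list(loops = loops, profile = do.call(rbind, prof),
                 segments = segments,
                 params = list(weight_mode = weight_mode,
                               cutoff_bins = if (is.null(cutoff_bins))
                                 ceiling(50000 / contacts$resolution)
                               else cutoff_bins,
                               const_a = const_a, components = components,
                               scale_eigen = scale_eigen,
                               window_bins = window_bins,
                               smooth_window = smooth_window,
                               min_window = min_window,
                               threshold_factor = threshold_factor,
                               threshold_on = threshold_on,
                               normalize = normalize),
                 chrom = contacts$chrom, resolution = contacts$resolution,
                 n_bins = n, call = cl),
            class = "mds_loops")
}

#' @export
print.mds_loops <- function(x, ...) {
  cat("MDS-based DNA-loop model\n")
  cat(sprintf("  %s: %d bins @ %d bp, %d segment(s)\n",
              x$chrom, x$n_bins, x$resolution, length(x$segments)))
  cat(sprintf("  weighting: %s (cutoff %d bins), components (%s)\n",
              x$params$weight_mode, x$params$cutoff_bins,
              paste(x$params$components, collapse = ", ")))
  fr <- loop_fraction(x$loops, x$n_bins)
  cat(sprintf("  loops called: %d; bins in loops: %d/%d = %s\n",
              nrow(x$loops$loops), fr$numerator, fr$denominator,
              fr$formatted))
  invisible(x)
}

#' @method summary mds_loops
#' @export
summary.mds_loops <- function(object, ...) {
  l <- object$loops$loops
  len_bp <- (l$right_root - l$left_root + 1L) * object$resolution
  out <- list(n_loops = nrow(l),
              mean_length_bp = if (nrow(l)) mean(len_bp) else NA_real_,
              loop_fraction = loop_fraction(object$loops, object$n_bins),
              thresholds = vapply(object$segments, `[[`, 0, "threshold"),
              params = object$params)
  class(out) <- "summary.mds_loops"
  out
}

#' @export
print.summary.mds_loops <- function(x, ...) {
  cat(sprintf("loops: %d, mean length %.0f bp\n", x$n_loops,
              x$mean_length_bp))
  cat("bins in loops: "); print(x$loop_fraction)
  cat(sprintf("segment thresholds: %s\n",
              paste(signif(x$thresholds, 4), collapse = ", ")))
  invisible(x)
}

#' @method coef mds_loops
#' @export
coef.mds_loops <- function(object, segment = 1L, ...) {
  object$segments[[segment]]$embedding$coords
}

#' Plot a fitted loop model
#'
#' `type = "profile"`: smoothed step-distance profile with the calling
#' threshold and called regions shaded; `type = "structure"`: the planar
#' embedding (tentative chromosome structure) with root bins highlighted.
#'
#' @param x An `mds_loops` fit.
#' @param type `"profile"` or `"structure"`.
#' @param segment Segment to plot for `"structure"`.
#' @param ... Passed to the underlying plot call.
#' @method plot mds_loops
#' @export
plot.mds_loops <- function(x, type = c("profile", "structure"),
                           segment = 1L, ...) {
  type <- match.arg(type)
  if (type == "profile") {
    p <- x$profile
    graphics::plot(p$bin, p$E_smooth, type = "l", xlab = "bin",
                   ylab = "smoothed step distance E'", ...)
    for (s in seq_along(x$segments)) {
      sel <- p$segment == s
      graphics::segments(min(p$bin[sel]), x$segments[[s]]$threshold,
                         max(p$bin[sel]), x$segments[[s]]$threshold,
                         col = "red")
    }
    l <- x$loops$loops
    if (nrow(l))
      graphics::rect(l$left_root, graphics::par("usr")[3],
                     l$right_root, graphics::par("usr")[4],
                     col = grDevices::adjustcolor("steelblue", 0.2),
                     border = NA)
  } else {
    co <- x$segments[[segment]]$embedding$coords
    graphics::plot(co, type = "l", col = "grey60",
                   xlab = sprintf("eigenvector v%d", x$params$components[1]),
                   ylab = sprintf("eigenvector v%d", x$params$components[2]),
                   ...)
    from <- x$segments[[segment]]$from
    l <- x$loops$loops
    roots <- c(l$left_root, l$right_root) - from + 1L
    roots <- roots[roots >= 1L & roots <= nrow(co)]
    graphics::points(co[roots, , drop = FALSE], col = "blue", pch = 19)
  }
  invisible(x)
}
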