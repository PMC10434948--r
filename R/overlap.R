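#' Select the top-scoring peaks
#'
#' Returns the `n` highest-score peaks (ChIP-seq/ATAC-seq), ties at the
#' cutoff broken by genomic position ascending, matching the "top 300 peaks"
#' selection used when validating loop calls.
#'
#' @param peaks data.frame from [read_peaks()] with a numeric `score`.
#' @param n Number of peaks to keep.
#' @return The selected rows, sorted by `(chrom, start)`.
#' @export
top_n_peaks <- function(peaks, n = 300L) {
  if (is.null(peaks$score) || all(is.na(peaks$score)))
    stop("peaks carry no scores; rank them upstream or pass all peaks explicitly")
  if (anyNA(peaks$score))
    stop("some peaks have missing scores; cannot rank")
  ord <- order(-peaks$score, peaks$chrom, peaks$start)
  keep <- ord[seq_len(min(n, nrow(peaks)))]
  out <- peaks[sort(keep), , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Observed-versus-expected base-pair overlap of loops with peaks
#'
#' Builds the 2x2 accounting used to test whether called loop regions match
#' peak locations. Peaks are merged (overlaps unioned) first. Observed cells:
#' base pairs of loop regions inside peaks, and the remainder of the loop
#' regions. Expected cells: the loop length apportioned by the genome-wide
#' peak proportion, `exp_peak = (peak_bp / genome_bp) * loop_bp`. Both rows
#' sum to the total loop length. The odds ratio is
#' `(obs_peak/obs_nonpeak) / (exp_peak/exp_nonpeak)` and the p-value comes
#' from [exact_test_2x2()] on the half-up-rounded cells.
#'
#' @param loops A `loop_set` or a data.frame `chrom`, `start`, `end` of loop
#'   regions (0-based half-open bp).
#' @param peaks data.frame of peak intervals (`chrom`, `start`, `end`).
#' @param genome_bp Total genome length in bp.
#' @return An object of class `overlap_table`: list with `obs_peak_bp`,
#'   `obs_nonpeak_bp`, `exp_peak_bp`, `exp_nonpeak_bp`, `loop_bp`, `peak_bp`,
#'   `odds_ratio`, `p_value`, `test`.
#' @export
overlap_table <- function(loops, peaks, genome_bp) {
  iv <- if (inherits(loops, "loop_set")) loop_intervals(loops) else loops
  stopifnot(all(c("chrom", "start", "end") %in% names(iv)),
            all(c("chrom", "start", "end") %in% names(peaks)))
  loop_ir <- .split_iranges(iv)
  peak_ir <- .split_iranges(peaks)
  loop_bp <- sum(vapply(loop_ir, function(x) sum(IRanges::width(x)), 0))
  peak_bp <- sum(vapply(peak_ir, function(x) sum(IRanges::width(x)), 0))
  if (genome_bp < peak_bp)
    stop("'genome_bp' smaller than the merged peak footprint")
  obs <- 0
  for (ch in intersect(names(loop_ir), names(peak_ir)))
    obs <- obs + sum(IRanges::width(
      IRanges::intersect(loop_ir[[ch]], peak_ir[[ch]])))
  ot <- overlap_table_from_cells(
    obs_peak_bp = obs, obs_nonpeak_bp = loop_bp - obs,
    exp_peak_bp = peak_bp / genome_bp * loop_bp,
    exp_nonpeak_bp = loop_bp - peak_bp / genome_bp * loop_bp)
  ot$peak_bp <- peak_bp
  ot
}

#' Odds ratio and test from explicit observed/expected cells
#'
#' The same statistic as [overlap_table()] computed directly from the four
#' cells of a printed observed-versus-expected table.
#'
#' @param obs_peak_bp,obs_nonpeak_bp Observed loop bp inside / outside peaks.
#' @param exp_peak_bp,exp_nonpeak_bp Expected split of the same loop bp.
#' @return An `overlap_table` object.
#' @export
overlap_table_from_cells <- function(obs_peak_bp, obs_nonpeak_bp,
                                     exp_peak_bp, exp_nonpeak_bp) {
  cells <- c(obs_peak_bp, obs_nonpeak_bp, exp_peak_bp, exp_nonpeak_bp)
  if (any(cells < 0)) stop("negative cell")
  or <- (obs_peak_bp / obs_nonpeak_bp) / (exp_peak_bp / exp_nonpeak_bp)
  if (obs_peak_bp == 0) or <- 0
  else if (obs_nonpeak_bp == 0 && exp_nonpeak_bp == 0)
    or <- obs_peak_bp / exp_peak_bp   # fully covered rows: odds cancel
  p <- exact_test_2x2(.round_half_up(obs_peak_bp), .round_half_up(obs_nonpeak_bp),
                      .round_half_up(exp_peak_bp), .round_half_up(exp_nonpeak_bp))
  structure(list(obs_peak_bp = obs_peak_bp, obs_nonpeak_bp = obs_nonpeak_bp,
                 exp_peak_bp = exp_peak_bp, exp_nonpeak_bp = exp_nonpeak_bp,
                 loop_bp = obs_peak_bp + obs_nonpeak_bp,
                 odds_ratio = or, p_value = as.numeric(p),
                 test = attr(p, "method")),
            class = "overlap_table")
}

.round_half_up <- function(x) floor(x + 0.5)

#' @export
print.overlap_table <- function(x, ...) {
  cat("observed vs expected loop/peak overlap [bp]\n")
  m <- matrix(c(x$obs_peak_bp, x$obs_nonpeak_bp,
                x$exp_peak_bp, x$exp_nonpeak_bp), 2, byrow = TRUE,
              dimnames = list(c("observed", "expected"),
                              c("peak", "non-peak")))
  print(format(m, big.mark = ",", scientific = FALSE), quote = FALSE)
  cat(sprintf("odds ratio %.4g, p %s %.4g (%s)\n", x$odds_ratio,
              if (x$test == "chisq") "~" else "=", x$p_value, x$test))
  invisible(x)
}

#' Two-sided exact test for a 2x2 table
#'
#' Fisher's exact probability test, computed by direct log-space enumeration
#' of the hypergeometric support: the two-sided p-value sums all tables with
#' the same margins whose probability does not exceed that of the observed
#' table (with a 1e-7 relative tolerance, the usual convention). When the
#' smallest table margin exceeds `exact_limit` the enumeration is replaced by
#' the chi-square test with continuity correction and the result is flagged
#' approximate — genome-scale bp tables are far beyond exact enumeration but
#' deep in the asymptotic regime.
#'
#' @param a,b,c,d Non-negative integer cells, row-wise
#'   (`matrix(c(a, b, c, d), 2, byrow = TRUE)`).
#' @param exact_limit Largest smallest-margin for which enumeration is used.
#' @return p-value in `[0, 1]` with attribute `method` = `"exact"` or
#'   `"chisq"`.
#' @export
exact_test_2x2 <- function(a, b, c, d, exact_limit = 1e4) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("negative count")
  if (any(abs(cells - round(cells)) > 1e-8))
    stop("counts must be integers (round upstream)")
  cells <- round(cells)
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (min(r1, r2, c1, c2) <= exact_limit) {
    lo <- max(0, c1 - r2); hi <- min(r1, c1)
    x <- lo:hi
    lp <- lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(r1 + r2, c1)
    p <- sum(exp(lp[lp <= lp[x == a] + log(1 + 1e-7)]))
    structure(min(max(p, 0), 1), method = "exact")
  } else {
    p <- suppressWarnings(stats::chisq.test(
      matrix(cells, 2, byrow = TRUE), correct = TRUE)$p.value)
    structure(min(max(p, 0), 1), method = "chisq")
  }
}

#' Count genes overlapping loop regions
#'
#' A gene counts as inside a loop when its interval overlaps any loop region
#' by at least 1 bp. Genes are deduplicated by `name` when present.
#'
#' @param genes data.frame of gene intervals (`chrom`, `start`, `end`,
#'   optional `name`).
#' @param loops A `loop_set` or interval data.frame.
#' @return List with `genes_in`, `genes_total` and a [report_fraction()]
#'   under `fraction`.
#' @export
count_genes_in_loops <- function(genes, loops) {
  if (!is.null(genes$name) && !all(is.na(genes$name))) {
    dup <- duplicated(genes$name) & !is.na(genes$name)
    genes <- genes[!dup, , drop = FALSE]
  }
  iv <- if (inherits(loops, "loop_set")) loop_intervals(loops) else loops
  loop_ir <- .split_iranges(iv)
  hit <- logical(nrow(genes))
  for (ch in unique(genes$chrom)) {
    sel <- genes$chrom == ch
    if (is.null(loop_ir[[ch]])) next
    g_ir <- IRanges::IRanges(start = genes$start[sel] + 1L,
                             end = genes$end[sel])
    hit[sel] <- IRanges::overlapsAny(g_ir, loop_ir[[ch]])
  }
  list(genes_in = sum(hit), genes_total = nrow(genes),
       fraction = report_fraction(sum(hit), nrow(genes)))
}
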