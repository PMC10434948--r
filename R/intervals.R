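#' Read peak or gene intervals from BED / narrowPeak text
#'
#' Both dialects are tab- (or whitespace-) delimited with 0-based half-open
#' coordinates. For `dialect = "BED"` the score is taken from column 5 when
#' present; for `"narrowPeak"` the BED score is column 5 and the peak caller's
#' `signalValue` (column 7) is also kept and used as the ranking score.
#' Records with `end <= start` are rejected with a warning. Output is sorted
#' by `(chrom, start)`.
#'
#' @param path Path to the interval file. `#`, `track` and `browser` lines are
#'   skipped.
#' @param dialect `"BED"` or `"narrowPeak"`.
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`, `score`
#'   (and `signalValue` for narrowPeak, duplicated into `score`).
#' @export
read_peaks <- function(path, dialect = c("BED", "narrowPeak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|track\\b|browser\\b|$)", lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = numeric()))
  fields <- strsplit(lines, "\\s+")
  if (any(lengths(fields) < 3L))
    stop("interval line with fewer than 3 columns")
  get <- function(k, default = NA_character_)
    vapply(fields, function(f) if (length(f) >= k) f[k] else default, "")
  chrom <- get(1)
  start <- suppressWarnings(as.integer(get(2)))
  end   <- suppressWarnings(as.integer(get(3)))
  if (anyNA(start) || anyNA(end)) stop("non-numeric interval coordinates")
  name  <- get(4)
  score <- suppressWarnings(as.numeric(get(5)))
  out <- data.frame(chrom = chrom, start = start, end = end,
                    name = name, score = score,
                    stringsAsFactors = FALSE)
  if (dialect == "narrowPeak") {
    sig <- suppressWarnings(as.numeric(get(7)))
    out$signalValue <- sig
    out$score <- ifelse(is.na(sig), out$score, sig)
  }
  bad <- out$end <= out$start
  if (any(bad)) {
    warning(sum(bad), " interval(s) with end <= start rejected")
    out <- out[!bad, , drop = FALSE]
  }
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write called loop regions as BED4
#'
#' One 0-based half-open BED line per loop region, spanning
#' `[left_root * resolution, (right_root + 1) * resolution)`, named
#' `loop_1, loop_2, ...` in start order.
#'
#' @param loops A [loop_set()].
#' @param path Output path.
#' @export
write_loops_bed <- function(loops, path) {
  stopifnot(inherits(loops, "loop_set"))
  iv <- loop_intervals(loops)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# loop regions, %s @ %d bp resolution",
                     loops$chrom, loops$resolution), con)
  if (nrow(iv))
    writeLines(sprintf("%s\t%d\t%d\tloop_%d",
                       iv$chrom, iv$start, iv$end, seq_len(nrow(iv))), con)
  invisible(NULL)
}

# per-chromosome merged IRanges from a chrom/start/end data.frame
# (BED half-open -> 1-based closed integers)
.split_iranges <- function(df, merge = TRUE) {
  sp <- split(df[c("start", "end")], df$chrom)
  lapply(sp, function(d) {
    ir <- IRanges::IRanges(start = d$start + 1L, end = d$end)
    if (merge) IRanges::reduce(ir) else ir
  })
}
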