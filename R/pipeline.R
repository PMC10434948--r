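#' Run the full file-to-file loop-calling pipeline
#'
#' Orchestrates the end-to-end analysis: read (or simulate) contacts,
#' normalize, fit [mds_loops()], write the loop BED, the per-bin profile TSV
#' and, when peaks are supplied, the observed-versus-expected overlap report;
#' when a gene annotation is supplied, the gene-in-loop counts. All outputs
#' are deterministic functions of the configuration.
#'
#' @param config Named list (see [default_config()]); any entry omitted falls
#'   back to the default. Paths: `contacts` (required), `peaks`, `genes`,
#'   `outdir` (required).
#' @return Invisibly, a list with the `mds_loops` fit, the summary, the
#'   `overlap_table` (or NULL) and the gene counts (or NULL).
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$contacts)) stop("config entry 'contacts' is required")
  if (is.null(cfg$outdir)) stop("config entry 'outdir' is required")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  fit <- mds_loops(cfg$contacts,
                   weight_mode = cfg$weight_mode,
                   cutoff_bins = if (is.null(cfg$cutoff_bp)) NULL
                                 else ceiling(cfg$cutoff_bp / cfg$resolution),
                   const_a = cfg$const_a,
                   components = cfg$components,
                   scale_eigen = cfg$scale_eigen,
                   window_bins = cfg$window_bins,
                   smooth_window = cfg$smooth_window,
                   min_window = cfg$min_window,
                   threshold_factor = cfg$threshold_factor,
                   threshold_on = cfg$threshold_on,
                   normalize = cfg$normalize,
                   resolution = cfg$resolution, chrom = cfg$chrom,
                   n_bins = cfg$n_bins)

  write_loops_bed(fit$loops, file.path(cfg$outdir, "loops.bed"))
  utils::write.table(fit$profile, file.path(cfg$outdir, "profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ov <- genes <- NULL
  if (!is.null(cfg$peaks)) {
    pk <- read_peaks(cfg$peaks, dialect = cfg$peak_dialect)
    pk <- top_n_peaks(pk, n = cfg$top_n)
    genome_bp <- if (is.null(cfg$genome_bp))
      as.numeric(fit$n_bins) * fit$resolution else cfg$genome_bp
    ov <- overlap_table(fit$loops, pk, genome_bp = genome_bp)
    cells <- data.frame(
      row = c("observed", "expected"),
      peak_bp = c(ov$obs_peak_bp, ov$exp_peak_bp),
      nonpeak_bp = c(ov$obs_nonpeak_bp, ov$exp_nonpeak_bp))
    utils::write.table(cells, file.path(cfg$outdir, "overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cat(sprintf("odds_ratio\t%.6g\np_value\t%.6g\ntest\t%s\n",
                ov$odds_ratio, ov$p_value, ov$test),
        file = file.path(cfg$outdir, "overlap.tsv"), append = TRUE)
  }
  if (!is.null(cfg$genes)) {
    gn <- read_peaks(cfg$genes, dialect = "BED")
    genes <- count_genes_in_loops(gn, fit$loops)
  }

  fr <- loop_fraction(fit$loops, fit$n_bins)
  summary_lines <- c(
    sprintf("loops\t%d", nrow(fit$loops$loops)),
    sprintf("bins_in_loops\t%d/%d = %s", fr$numerator, fr$denominator,
            fr$formatted),
    if (!is.null(genes))
      sprintf("genes_in_loops\t%d/%d = %s", genes$genes_in,
              genes$genes_total, genes$fraction$formatted),
    if (!is.null(ov))
      sprintf("odds_ratio\t%.4f", ov$odds_ratio))
  writeLines(summary_lines, file.path(cfg$outdir, "summary.tsv"))
  write_config(cfg, file.path(cfg$outdir, "config.txt"))

  invisible(list(fit = fit, loop_fraction = fr, overlap = ov, genes = genes))
}

#' Default pipeline configuration
#'
#' The defaults reproduce the reference settings: 10 kb resolution, 50 kbp
#' weighting cutoff, log weighting, eigenvector ranks 2-3, 10-step smoothing
#' with 5-step boundary minimum, threshold factor 2, top 300 peaks, human
#' genome length 3,186,000,000 bp for the expected-overlap proportion.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(contacts = NULL, peaks = NULL, genes = NULL, outdir = NULL,
       chrom = "chr1", resolution = 10000L, n_bins = "infer",
       normalize = TRUE, weight_mode = "log", cutoff_bp = 50000L,
       const_a = NULL, components = c(2L, 3L), scale_eigen = FALSE,
       window_bins = 5000L, smooth_window = 10L, min_window = 5L,
       threshold_factor = 2, threshold_on = "smooth",
       peak_dialect = "narrowPeak", top_n = 300L, genome_bp = 3186000000)
}

#' Read / write a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` comments allowed. Vector values are
#' comma-separated. A written configuration re-read through `read_config()`
#' reproduces the run.
#'
#' @param path File path.
#' @return `read_config()`: named list with parsed numeric/logical scalars.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0L)) stop("malformed config line: ", lines[eq < 0L][1L])
  keys <- trimws(substr(lines, 1L, eq - 1L))
  vals <- trimws(substr(lines, eq + 1L, nchar(lines)))
  if (any(keys == "")) stop("malformed config line: missing key")
  stats::setNames(lapply(vals, .parse_scalar), keys)
}

.parse_scalar <- function(x) {
  if (x %in% c("NULL", "")) return(NULL)
  if (grepl(",", x, fixed = TRUE))
    return(unlist(lapply(strsplit(x, ",")[[1]], .parse_scalar)))
  if (x %in% c("TRUE", "FALSE")) return(as.logical(x))
  n <- suppressWarnings(as.numeric(x))
  if (!is.na(n)) return(if (n == round(n) && abs(n) < 2^31) as.integer(n) else n)
  x
}

#' @rdname read_config
#' @param config Named list of scalar (or short vector) values.
#' @export
write_config <- function(config, path) {
  fmt <- vapply(config, function(v) {
    if (is.null(v)) "NULL" else paste(format(v, scientific = FALSE,
                                             trim = TRUE), collapse = ",")
  }, "")
  writeLines(paste(names(config), "=", fmt), path)
  invisible(NULL)
}
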