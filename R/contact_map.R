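#' Sparse binned Hi-C contact map
#'
#' Container for cis contact frequencies of one chromosome (segment) at a fixed
#' bin resolution. Storage is sparse upper-triangular: each record is a
#' `(i, j, value)` triplet with 0-based bin indices, `i <= j`, and `value >= 0`.
#' Pairs absent from the record set are semantically zero: missing values in
#' Hi-C data are treated as zero contacts so that looped and loop-free DNA
#' separate cleanly downstream.
#'
#' Duplicate `(i, j)` keys (including mirrored `(j, i)` input) are summed with
#' a warning.
#'
#' @param i,j Integer vectors of 0-based bin indices.
#' @param value Numeric vector of non-negative contact frequencies.
#' @param n_bins Number of bins; `"infer"` takes `max(i, j) + 1`.
#' @param resolution Bin width in bp.
#' @param chrom Chromosome label.
#' @param normalized Logical flag: has coverage normalization been applied?
#' @return An object of class `contact_map`: a list with elements `records`
#'   (data.frame `i`, `j`, `value`), `n_bins`, `resolution`, `chrom`,
#'   `normalized`.
#' @seealso [read_contacts()], [vc_normalize()], [mds_loops()]
#' @export
contact_map <- function(i = integer(), j = integer(), value = numeric(),
                        n_bins = "infer", resolution = 10000L,
                        chrom = "chr1", normalized = FALSE) {
  stopifnot(length(i) == length(j), length(j) == length(value))
  if (length(resolution) != 1L || !is.finite(resolution) || resolution <= 0)
    stop("'resolution' must be a single positive number")
  i <- as.integer(i); j <- as.integer(j); value <- as.numeric(value)
  if (anyNA(i) || anyNA(j) || anyNA(value))
    stop("contact records must not contain NA")
  if (any(value < 0)) stop("contact values must be non-negative")
  if (any(i < 0L) || any(j < 0L)) stop("bin indices must be non-negative")

  # canonical i <= j
  swap <- i > j
  if (any(swap)) {
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  }
  if (identical(n_bins, "infer")) {
    if (length(i) == 0L)
      stop("cannot infer 'n_bins' from an empty record set")
    n_bins <- max(j) + 1L
  }
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("'n_bins' must be positive")
  if (length(j) && max(j) >= n_bins)
    stop("bin index ", max(j), " outside [0, n_bins)")

  if (anyDuplicated(cbind(i, j))) {
    warning("duplicate (i, j) records summed")
    key <- paste(i, j)
    value <- as.numeric(tapply(value, key, sum)[unique(key)])
    keep <- !duplicated(key)
    i <- i[keep]; j <- j[keep]
  }
  ord <- order(i, j)
  structure(
    list(records = data.frame(i = i[ord], j = j[ord], value = value[ord]),
         n_bins = n_bins, resolution = as.integer(resolution),
         chrom = chrom, normalized = isTRUE(normalized)),
    class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %s, %d bins @ %d bp (%s)\n",
              x$chrom, x$n_bins, x$resolution,
              if (x$normalized) "VC-normalized" else "raw"))
  cat(sprintf("  %d stored records, total (full-matrix) sum %.6g\n",
              nrow(x$records), contact_sum(x)))
  invisible(x)
}

# sum over the full symmetric matrix (off-diagonal records count twice)
contact_sum <- function(cm) {
  r <- cm$records
  sum(r$value * ifelse(r$i == r$j, 1, 2))
}

#' Dense symmetric matrix view of a contact map
#'
#' @param cm A `contact_map`.
#' @return An `n_bins x n_bins` numeric matrix with zeros for absent pairs.
#' @export
as_dense <- function(cm) {
  stopifnot(inherits(cm, "contact_map"))
  n <- cm$n_bins
  m <- matrix(0, n, n)
  r <- cm$records
  if (nrow(r)) {
    m[cbind(r$i + 1L, r$j + 1L)] <- r$value
    m[cbind(r$j + 1L, r$i + 1L)] <- r$value
  }
  m
}

#' Read sparse Hi-C contact triplets
#'
#' Reads whitespace/tab-delimited triplet text (`pos_i pos_j count`), the
#' format produced by straw-style dumps of `.hic` files. Coordinates are
#' auto-detected: if any position is `>= resolution` the columns are taken as
#' bp positions and floored to bin indices by integer division by
#' `resolution`; otherwise they are taken as bin indices directly. Lines
#' starting with `#` and blank lines are skipped.
#'
#' @param path Path to the triplet file.
#' @param resolution Bin width in bp.
#' @param chrom Chromosome label to attach.
#' @param n_bins Number of bins, or `"infer"` (max bin index + 1).
#' @return A [contact_map()].
#' @export
read_contacts <- function(path, resolution = 10000L, chrom = "chr1",
                          n_bins = "infer") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (resolution <= 0) stop("'resolution' must be positive")
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) {
    if (identical(n_bins, "infer"))
      stop("empty contact file and n_bins = \"infer\"")
    return(contact_map(n_bins = n_bins, resolution = resolution,
                       chrom = chrom))
  }
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed contact line ", idx[which(nf < 3L)[1L]],
         ": expected 3 whitespace-separated fields")
  m <- matrix(suppressWarnings(as.numeric(unlist(
    lapply(fields, `[`, 1:3)))), ncol = 3, byrow = TRUE)
  bad <- which(!stats::complete.cases(m) | !is.finite(rowSums(m)))
  if (length(bad))
    stop("malformed contact line ", idx[bad[1L]], ": non-numeric field")
  if (any(m[, 3] < 0))
    stop("malformed contact line ", idx[which(m[, 3] < 0)[1L]],
         ": negative count")
  pos <- m[, 1:2, drop = FALSE]
  if (any(pos >= resolution)) {            # bp positions
    off <- pos %% resolution != 0
    if (any(off))
      warning(sum(off), " position(s) not a multiple of the resolution; floored")
    bins <- floor(pos / resolution)
  } else {
    bins <- pos
  }
  contact_map(i = bins[, 1], j = bins[, 2], value = m[, 3],
              n_bins = n_bins, resolution = resolution, chrom = chrom)
}

#' Write a contact map as sparse triplets
#'
#' Inverse of [read_contacts()]: one `pos_i pos_j value` line per stored
#' record, tab-separated. With `coords = "bp"` bin indices are multiplied by
#' the resolution (straw-style dump); with `"bins"` raw indices are written.
#'
#' @param cm A `contact_map`.
#' @param path Output path.
#' @param coords `"bp"` or `"bins"`.
#' @export
write_contacts <- function(cm, path, coords = c("bp", "bins")) {
  stopifnot(inherits(cm, "contact_map"))
  coords <- match.arg(coords)
  r <- cm$records
  f <- if (coords == "bp") as.numeric(cm$resolution) else 1
  writeLines(sprintf("%.0f\t%.0f\t%s", r$i * f, r$j * f,
                     format(r$value, digits = 15, scientific = FALSE,
                            trim = TRUE)), path)
  invisible(NULL)
}

#' Vanilla-coverage normalization
#'
#' Divides each contact by the product of its row and column coverage sums of
#' the full symmetric matrix, `c_ij / (s_i * s_j)`, then rescales globally so
#' the total matrix sum is preserved. Bins with zero coverage keep all-zero
#' rows.
#'
#' @param cm A raw `contact_map`.
#' @return A `contact_map` with `normalized = TRUE`.
#' @export
vc_normalize <- function(cm) {
  stopifnot(inherits(cm, "contact_map"))
  if (cm$normalized) stop("contact map is already normalized")
  r <- cm$records
  tot <- contact_sum(cm)
  if (tot == 0) {
    warning("all-zero contact map; returned unchanged")
    cm$normalized <- TRUE
    return(cm)
  }
  off <- r$i != r$j
  s <- numeric(cm$n_bins)
  acc_i <- tapply(r$value, r$i, sum)
  acc_j <- tapply(r$value[off], r$j[off], sum)
  s[as.integer(names(acc_i)) + 1L] <- acc_i
  if (length(acc_j)) {
    jj <- as.integer(names(acc_j)) + 1L
    s[jj] <- s[jj] + acc_j
  }
  v <- r$value
  denom <- s[r$i + 1L] * s[r$j + 1L]
  pos <- denom > 0 & v > 0
  v[pos] <- v[pos] / denom[pos]
  v[!pos] <- 0
  new_tot <- sum(v * ifelse(off, 2, 1))
  if (new_tot > 0) v <- v * tot / new_tot
  cm$records$value <- v
  cm$normalized <- TRUE
  cm
}

# restrict a contact map to bins [from, to] (0-based, inclusive), reindexed to 0
slice_contacts <- function(cm, from, to) {
  r <- cm$records
  keep <- r$i >= from & r$j <= to
  contact_map(i = r$i[keep] - from, j = r$j[keep] - from,
              value = r$value[keep], n_bins = to - from + 1L,
              resolution = cm$resolution, chrom = cm$chrom,
              normalized = cm$normalized)
}
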