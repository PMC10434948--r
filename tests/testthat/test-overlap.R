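make_peaks <- function(n, seed = 1, chrom = "chr1") {
  set.seed(seed)
  start <- sort(sample.int(1e6, n)) * 10L
  data.frame(chrom = chrom, start = start, end = start + 500L,
             name = paste0("p", seq_len(n)), score = round(runif(n, 1, 1000)))
}

test_that("top-N peak selection keeps the highest scores with positional ties", {
  pk <- make_peaks(500, seed = 2)
  top <- top_n_peaks(pk, 300)
  expect_equal(nrow(top), 300L)
  expect_gte(min(top$score), max(pk$score[!pk$name %in% top$name]))

  expect_equal(nrow(top_n_peaks(make_peaks(100), 300)), 100L)

  # two equal scores at the cutoff boundary: leftmost kept
  pk2 <- data.frame(chrom = "chr1", start = c(5000, 1000, 9000),
                    end = c(5100, 1100, 9100), name = c("a", "b", "c"),
                    score = c(10, 7, 7))
  top2 <- top_n_peaks(pk2, 2)
  expect_setequal(top2$name, c("a", "b"))

  pk$score <- NA
  expect_error(top_n_peaks(pk, 10), "score")
})

test_that("the observed-versus-expected table reproduces the printed odds ratio", {
  ot <- overlap_table_from_cells(2410018.00, 315969982.00,
                                 61730.32, 318318270.00)
  expect_equal(round(ot$odds_ratio, 2), 39.33)
  expect_lt(ot$p_value, 2.2e-16)
  expect_equal(ot$test, "chisq")   # margins far beyond exact enumeration
  # rows both sum to the loop length
  expect_equal(ot$obs_peak_bp + ot$obs_nonpeak_bp, ot$loop_bp)
  expect_equal(ot$exp_peak_bp + ot$exp_nonpeak_bp, ot$loop_bp, tolerance = 1e-6)
})

test_that("overlap accounting handles disjoint, identical and fragmented peaks", {
  loops <- loop_set(data.frame(left_root = c(10L, 40L),
                               right_root = c(19L, 49L)),
                    chrom = "chr1", resolution = 10000L)
  # loops cover [100000,200000) and [400000,500000): 200 kb
  peaks_in <- data.frame(chrom = "chr1", start = c(150000, 410000),
                         end = c(160000, 420000))
  ot <- overlap_table(loops, peaks_in, genome_bp = 1e7)
  expect_equal(ot$obs_peak_bp, 20000)
  expect_equal(ot$exp_peak_bp, 20000 / 1e7 * 200000)

  # fragmentation invariance: split one peak into abutting pieces
  frag <- data.frame(chrom = "chr1",
                     start = c(150000, 155000, 410000, 415000),
                     end = c(155000, 160000, 415000, 420000))
  ot2 <- overlap_table(loops, frag, genome_bp = 1e7)
  expect_equal(ot2$obs_peak_bp, ot$obs_peak_bp)
  expect_equal(ot2$odds_ratio, ot$odds_ratio)

  disj <- data.frame(chrom = "chr1", start = 900000, end = 910000)
  expect_equal(overlap_table(loops, disj, genome_bp = 1e7)$odds_ratio, 0)

  # loops == peaks == whole genome: no enrichment
  whole <- data.frame(chrom = "chr1", start = 0, end = 1e6)
  ot3 <- overlap_table(whole, whole, genome_bp = 1e6)
  expect_equal(ot3$odds_ratio, 1)

  expect_error(overlap_table(loops, whole, genome_bp = 1e5), "genome_bp")
})

test_that("the odds ratio is scale-free in the table cells", {
  base <- overlap_table_from_cells(120, 880, 40, 960)
  for (s in c(3, 17.5, 1000)) {
    scaled <- overlap_table_from_cells(120 * s, 880 * s, 40 * s, 960 * s)
    expect_equal(scaled$odds_ratio, base$odds_ratio, tolerance = 1e-12)
  }
})

test_that("the exact test matches enumeration and fisher.test oracles", {
  # frozen from the enumeration oracle (also stats::fisher.test)
  expect_equal(as.numeric(exact_test_2x2(1, 9, 11, 3)), 0.0027594562,
               tolerance = 1e-7)
  expect_equal(as.numeric(exact_test_2x2(5, 5, 5, 5)), 1)
  expect_equal(as.numeric(exact_test_2x2(0, 10, 10, 0)),
               fisher_oracle(0, 10, 10, 0), tolerance = 1e-12)

  set.seed(99)
  for (rep. in 1:40) {
    tab <- as.vector(stats::rmultinom(1, sample(10:120, 1), runif(4, 0.05, 1)))
    ours <- as.numeric(do.call(exact_test_2x2, as.list(tab)))
    expect_equal(ours, fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-10)
    expect_equal(ours,
                 stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-7)
  }

  big <- exact_test_2x2(2e5, 8e5, 1e5, 9e5)
  expect_equal(attr(big, "method"), "chisq")
  expect_lt(as.numeric(big), 1e-10)
  expect_error(exact_test_2x2(-1, 2, 3, 4), "negative")
})

test_that("gene counting uses >= 1 bp overlap and printed counts format", {
  loops <- loop_set(data.frame(left_root = 10L, right_root = 19L),
                    chrom = "chr1", resolution = 10000L)  # [100000, 200000)
  genes <- data.frame(chrom = "chr1",
                      start = c(120000, 99000, 200000, 50000),
                      end = c(130000, 100001, 210000, 60000),
                      name = c("inside", "edge1bp", "after_end", "far"))
  gc <- count_genes_in_loops(genes, loops)
  expect_equal(gc$genes_in, 2L)   # inside + 1 bp boundary overlap
  expect_equal(gc$genes_total, 4L)

  # duplicated identifiers collapse
  gc2 <- count_genes_in_loops(rbind(genes, genes[1, ]), loops)
  expect_equal(gc2$genes_total, 4L)

  expect_equal(report_fraction(5002, 21306)$formatted, "0.235")
})
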