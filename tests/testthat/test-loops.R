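test_that("step distances are Euclidean and isometry-invariant", {
  expect_equal(step_distances(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(step_distances(rbind(c(1, 2), c(1, 2))), 0)
  set.seed(42)
  co <- matrix(rnorm(60), ncol = 2)
  E <- step_distances(co)
  for (th in c(0.3, 1.1, 2.5)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    expect_equal(step_distances(co %*% R), E, tolerance = 1e-12)
  }
  expect_equal(step_distances(co %*% diag(c(-1, 1))), E, tolerance = 1e-12)
})

test_that("smoothing matches the brute-force sliding-window oracle", {
  expect_equal(smooth_profile(rep(3, 25)), rep(3, 25))

  spike <- c(rep(0, 19), 10)
  expect_equal(smooth_profile(spike, 10, 5), smooth_oracle(spike, 10, 5))

  set.seed(7)
  for (M in c(10, 11, 14, 20, 53, 200)) {
    E <- rexp(M)
    expect_equal(smooth_profile(E, 10, 5), smooth_oracle(E, 10, 5),
                 tolerance = 1e-12)
  }
  # smoothed values stay within their source window's range
  E <- rexp(60)
  Es <- smooth_profile(E, 10, 5)
  for (i in seq_along(Es)) {
    win <- E[max(1, i - 10):min(60, i + 10)]
    expect_gte(Es[i], min(win) - 1e-12)
    expect_lte(Es[i], max(win) + 1e-12)
  }
  expect_warning(short <- smooth_profile(1:4, 10, 5), "global mean")
  expect_equal(short, rep(2.5, 4))
})

test_that("loop calling follows the hand-traced root-extension rules", {
  # nothing exceeds twice its own mean on a constant profile
  expect_equal(nrow(call_loops(rep(2, 30))$loops), 0L)

  # single spike: core at position 4 (1-based), roots at the flanking
  # local minima -> profile positions 3 and 5 -> bins 2 and 4
  ls <- call_loops(c(1, 1, 1, 9, 1, 1, 1))
  expect_equal(ls$threshold, 2 * 15 / 7)
  expect_equal(as.data.frame(ls), data.frame(left_root = 2L, right_root = 4L))
  expect_equal(ls$loops$above_bins[[1]], 3L)

  # descending flanks: walks stop at the first local minima
  prof <- c(5, 4, 3, 20, 6, 5, 4, 4.5, 1, 1)
  ls2 <- call_loops(prof)   # T = 10.5; only position 4 above
  # left: 3 < 20, then 4 >= 3 -> root at position 3 (bin 2)
  # right: 6,5,4 then 4.5 rises -> root at position 7 (bin 6)
  expect_equal(as.data.frame(ls2),
               data.frame(left_root = 2L, right_root = 6L))
})

test_that("adjacent cores are capped at the gap midpoint and may merge", {
  # cores at positions 4 and 12; the gap minimum (position 6) roots the
  # first region, the second region's left walk is capped at the midpoint
  prof <- c(1, 1, 1, 30, 5, 2, 4, 5, 6, 7, 8, 30, 1, 1, 1)
  ls <- call_loops(prof)
  df <- as.data.frame(ls)
  expect_equal(df, data.frame(left_root = c(2L, 7L),
                              right_root = c(5L, 12L)))
  expect_true(all(df$left_root[-1] > df$right_root[-nrow(df)]))

  # symmetric gap whose minimum falls exactly on the shared midpoint:
  # both walks root there and the regions merge into one
  prof_m <- c(1, 1, 1, 30, 5, 4, 3, 2, 3, 4, 5, 30, 1, 1, 1)
  df_m <- as.data.frame(call_loops(prof_m))
  expect_equal(df_m, data.frame(left_root = 2L, right_root = 12L))

  # even gap with its minimum exactly at the shared midpoint: both walks
  # root there and the two regions merge into one
  prof2 <- c(1, 20, 9, 8, 3, 8, 9, 25, 1, 1)
  ls2 <- call_loops(prof2)     # T = 17; cores at positions 2 and 8
  expect_equal(as.data.frame(ls2),
               data.frame(left_root = 0L, right_root = 8L))
  expect_setequal(ls2$loops$above_bins[[1]], c(1L, 7L))
})

test_that("every root lies at or below the threshold away from boundaries", {
  set.seed(31)
  for (rep. in 1:20) {
    prof <- rexp(80) + c(rep(0, 30), rep(3, 6), rep(0, 44)) * runif(1, 0, 3)
    ls <- call_loops(prof)
    l <- ls$loops
    if (!nrow(l)) next
    roots <- c(l$left_root, l$right_root) + 1L
    interior <- roots > 1 & roots < 80
    core_bins <- unlist(l$above_bins) + 1L
    chk <- setdiff(roots[interior], core_bins)
    expect_true(all(prof[chk] <= ls$threshold))
    # above-threshold positions all belong to exactly one loop
    expect_setequal(core_bins, which(prof > ls$threshold))
    expect_equal(anyDuplicated(core_bins), 0L)
  }
})

test_that("loop calls are invariant to global scaling of the coordinates", {
  set.seed(13)
  co <- matrix(rnorm(400), ncol = 2)
  co[101:130, ] <- co[101:130, ] * 6   # spread-out excursion
  E <- smooth_profile(step_distances(co))
  base <- as.data.frame(call_loops(E))
  for (s in c(0.01, 3, 1e4)) {
    scaled <- as.data.frame(call_loops(smooth_profile(step_distances(co * s))))
    expect_identical(scaled, base)
  }
  expect_gt(nrow(base), 0L)
})

test_that("a planted embedding excursion is called as one loop", {
  set.seed(5)
  n <- 200
  co <- matrix(rnorm(2 * n, 0, 0.05), ncol = 2)
  co[80:120, ] <- co[80:120, ] * 40    # long excursion with big steps
  Es <- smooth_profile(step_distances(co))
  ls <- call_loops(Es)
  expect_equal(nrow(ls$loops), 1L)
  expect_setequal(ls$loops$above_bins[[1]], which(Es > ls$threshold) - 1L)
  rec <- loop_recovery(ls, loop_set(data.frame(left_root = 79L,
                                               right_root = 119L)))
  expect_gte(rec$jaccard, 0.5)
})

test_that("coverage bookkeeping reports exact bin fractions", {
  ls <- loop_set(data.frame(left_root = c(2L, 10L), right_root = c(5L, 14L)),
                 n_bins = 50L)
  fr <- loop_fraction(ls)
  expect_equal(fr$numerator, 9)
  expect_equal(fr$fraction, 9 / 50)
  expect_equal(fr$formatted, "0.180")
  expect_equal(report_fraction(31860, 318380)$formatted, "0.100")
})
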