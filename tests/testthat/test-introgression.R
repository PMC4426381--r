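stats_from_counts <- function(counts, chrom = "chr1", ws = 1e6,
                              gap = rep(FALSE, length(counts))) {
  n <- length(counts)
  tibble::tibble(chrom = chrom, start = (seq_len(n) - 1) * ws,
                 end = seq_len(n) * ws, snp_count = counts,
                 indel_count = 0L, gene_count_halfMb = NA_integer_,
                 gap_fraction = as.numeric(gap), gap_flagged = gap)
}

test_that("qualifying windows merge across small non-qualifying gaps", {
  st <- stats_from_counts(c(1, 1, 9, 9, 1, 9, 1))
  seg <- call_dense_segments(st, high_threshold = 5, merge_gap = 1)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start, 2e6)
  expect_equal(seg$end, 6e6)
  expect_equal(seg$n_windows, 4L)
  none <- call_dense_segments(stats_from_counts(rep(1, 7)), 5, 1)
  expect_equal(nrow(none), 0L)
})

test_that("gap-flagged windows never seed and always break a merge", {
  gap <- c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  st <- stats_from_counts(c(1, 1, 9, 0, 9, 1, 1), gap = gap)
  seg <- call_dense_segments(st, 5, merge_gap = 1)
  expect_equal(nrow(seg), 2L)  # the N-window splits the run
  st2 <- stats_from_counts(c(9, 9, 9), gap = c(FALSE, TRUE, FALSE))
  # a gap window with a high count must not seed
  st2$snp_count[2] <- 99
  seg2 <- call_dense_segments(st2, 5, 0)
  expect_equal(nrow(seg2), 2L)
})

test_that("raising the threshold never enlarges a segment footprint", {
  set.seed(7)
  st <- stats_from_counts(sample(0:12, 40, replace = TRUE))
  lo <- call_dense_segments(st, 5, 1)
  hi <- call_dense_segments(st, 8, 1)
  cover <- function(seg) {
    unlist(lapply(seq_len(nrow(seg)), function(i) seq(seg$start[i], seg$end[i] - 1, 1e6)))
  }
  expect_true(all(cover(hi) %in% cover(lo)))
})

test_that("cross-line patterns map onto the four segment classes", {
  bg_a <- rep(800, 30); bg_b <- rep(8000, 30)
  mk <- function(a_val, b_val, at = 11:13) {
    a <- bg_a; b <- bg_b
    a[at] <- a_val; b[at] <- b_val
    list(a = stats_from_counts(a), b = stats_from_counts(b))
  }
  cls <- function(x) classify_segments(x$a, x$b)$pattern_class
  expect_equal(cls(mk(10000, 20000)), "reference_divergent")
  expect_equal(cls(mk(6000, 50)), "reference_from_wild")
  expect_equal(cls(mk(6000, 8000)), "lineA_specific")
  expect_equal(cls(mk(800, 30000)), "lineB_divergent")
  seg <- classify_segments(mk(10000, 20000)$a, mk(10000, 20000)$b)
  expect_match(seg$note, "transferred")
  # mismatched grids are rejected
  expect_error(classify_segments(stats_from_counts(bg_a),
                                 stats_from_counts(bg_b[1:20])), "grids")
})

test_that("third-line concordance is a majority vote over segment windows", {
  seg <- tibble::tibble(chrom = "chr1", start = 10e6, end = 12e6)
  third_hi <- stats_from_counts(c(rep(100, 10), 9000, 9000, rep(100, 3)))
  third_lo <- stats_from_counts(rep(100, 15))
  expect_true(third_line_concordance(seg[1, ], third_hi, 5000))
  expect_false(third_line_concordance(seg[1, ], third_lo, 5000))
  # exactly half of the windows elevated counts as concordant
  third_half <- stats_from_counts(c(rep(100, 10), 9000, 100, rep(100, 3)))
  expect_true(third_line_concordance(seg[1, ], third_half, 5000))
})

test_that("planted segments of all four classes are recovered on one fixture", {
  fix <- fix_density()
  sa <- window_stats(fix$lineA, fix$genome, NULL)
  sb <- window_stats(fix$lineB, fix$genome, NULL)
  seg <- classify_segments(sa, sb)
  truth <- fix$manifest$segments
  expect_equal(nrow(seg), nrow(truth))
  for (i in seq_len(nrow(truth))) {
    hit <- seg[seg$chrom == truth$chrom[i] &
                 seg$start < truth$end[i] & seg$end > truth$start[i], ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$pattern_class, truth$pattern_class[i])
    expect_lte(abs(hit$start - truth$start[i]), 1e6)
    expect_lte(abs(hit$end - truth$end[i]), 1e6)
  }
})
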