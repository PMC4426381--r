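snp_at <- function(pos, chrom = "chr1") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = "A", alt = "T",
                 genotype = "hom_alt", var_class = "snp")
}

test_that("window assignment follows the half-open anchored grid", {
  # 1-based positions: 1000000 is the last base of window 1, 1000001 the
  # first base of window 2
  v <- snp_at(c(1, 1000000, 1000001, 1500001, 2000001))
  wc <- window_counts(v, c(chr1 = 2100000), window_size = 1e6)
  expect_equal(wc$snp_count, c(2L, 2L, 1L))
  expect_equal(wc$start, c(0, 1e6, 2e6))
  expect_equal(wc$end[3], 2100000)  # last window short
})

test_that("an empty stream yields all-zero windows and unknown chroms error", {
  empty <- snp_at(integer(0))
  wc <- window_counts(empty, c(chr1 = 3e6), 1e6)
  expect_equal(wc$snp_count, rep(0L, 3))
  expect_equal(wc$indel_count, rep(0L, 3))
  expect_error(window_counts(snp_at(5, chrom = "chrZ"), c(chr1 = 3e6), 1e6),
               "chrZ")
})

test_that("window counts conserve totals and refine from 0.5 Mb to 1 Mb", {
  fix <- fix_default()
  cl <- chrom_lengths_of(fix)
  for (v in list(fix$lineA, fix$lineB)) {
    w1 <- window_counts(v, cl, 1e6)
    w2 <- window_counts(v, cl, 5e5)
    expect_equal(sum(w1$snp_count), sum(v$var_class == "snp"))
    expect_equal(sum(w2$snp_count), sum(v$var_class == "snp"))
    expect_equal(sum(w1$indel_count),
                 sum(v$var_class %in% c("insertion", "deletion")))
    agg <- dplyr::mutate(w2, parent = (start %/% 1e6) * 1e6) |>
      dplyr::group_by(chrom, parent) |>
      dplyr::summarise(snp = sum(snp_count), .groups = "drop") |>
      dplyr::arrange(chrom, parent)
    expect_equal(agg$snp, w1$snp_count)
  }
})

test_that("relative chromosome densities scale to the densest chromosome", {
  v <- dplyr::bind_rows(snp_at(seq_len(100) * 10, "chr1"),
                        snp_at(seq_len(50) * 10, "chr2"))
  d <- chromosome_relative_density(v, c(chr1 = 1e6, chr2 = 1e6))
  expect_equal(d$relative_snp, c(1, 0.5))
  one <- chromosome_relative_density(snp_at(5), c(chr1 = 1e6))
  expect_equal(one$relative_snp, 1)
  expect_error(chromosome_relative_density(snp_at(integer(0)), c(chr1 = 1e6)),
               "at least one")
  expect_error(chromosome_relative_density(snp_at(5), c(chr1 = 0)), "zero-length")
})

test_that("gene-rich windows require strictly more than the threshold", {
  mk <- function(n) {
    gene_models(
      tibble::tibble(gene_id = paste0("g", seq_len(n)), chrom = "chr1",
                     strand = "+", start = seq_len(n) * 100L,
                     end = seq_len(n) * 100L + 50L, complete = TRUE),
      tibble::tibble(gene_id = paste0("g", seq_len(n)), chrom = "chr1",
                     start = seq_len(n) * 100L, end = seq_len(n) * 100L + 50L),
      tibble::tibble(gene_id = paste0("g", seq_len(n)), chrom = "chr1",
                     start = seq_len(n) * 100L, end = seq_len(n) * 100L + 30L,
                     phase = 0L)
    )
  }
  w51 <- gene_rich_windows(mk(51), c(chr1 = 1e6))
  expect_true(w51$gene_rich[1])
  w50 <- gene_rich_windows(mk(50), c(chr1 = 1e6))
  expect_false(w50$gene_rich[1])
})

test_that("gap fractions follow the planted N-run arithmetic", {
  g <- Biostrings::DNAStringSet(c(
    chr1 = paste0(strrep("A", 100), strrep("N", 100), strrep("A", 200))
  ))
  gw <- gap_windows(g, window_size = 100, flag_threshold = 0.5)
  expect_equal(gw$gap_fraction, c(0, 1, 0, 0))
  expect_equal(gw$gap_flagged, c(FALSE, TRUE, FALSE, FALSE))
  # default fixture: chr2 run spans 1.6 windows of the 1-Mb grid
  fix <- fix_density()
  gw <- gap_windows(fix$genome, 1e6)
  chr2 <- gw[gw$chrom == "chr2", ]
  expect_equal(chr2$gap_fraction[3], 0.6)
  expect_equal(chr2$gap_fraction[4], 1.0)
})

test_that("InDel window counts track gene accumulation on the arms", {
  fix <- fix_default()
  ws <- window_stats(fix$lineA, fix$genome, fix$gm, window_size = 1e6)
  ok <- !ws$gap_flagged
  expect_gt(stats::cor(ws$indel_count[ok], ws$gene_count_halfMb[ok]), 0)
})
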