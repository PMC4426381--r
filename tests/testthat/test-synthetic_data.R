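test_that("genome generation is deterministic with planted gaps and flat GC", {
  g1 <- generate_genome(5, n_chrom = 1, chrom_length = 1e6,
                        gap_spec = tibble::tibble(chrom = "chr1",
                                                  start = 200001L, end = 300000L))
  g2 <- generate_genome(5, n_chrom = 1, chrom_length = 1e6,
                        gap_spec = tibble::tibble(chrom = "chr1",
                                                  start = 200001L, end = 300000L))
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  s <- g1$genome[[1]]
  expect_equal(as.character(Biostrings::subseq(s, 200001, 200005)), "NNNNN")
  freq <- Biostrings::letterFrequency(s, c("G", "C", "A", "T"))
  gc <- sum(freq[c("G", "C")]) / sum(freq)
  expect_gt(gc, 0.49); expect_lt(gc, 0.51)
  expect_error(generate_genome(5, n_chrom = 1, chrom_length = 1e6,
                               gap_spec = tibble::tibble(chrom = "chr1",
                                                         start = 1L, end = 2e6)),
               "longer than chromosome")
})

test_that("generated gene models are clean ORFs with the planted densities", {
  fix <- fix_default()
  gm <- fix$gm
  set.seed(1)
  for (gid in sample(gm$genes$gene_id, 30)) {
    cds <- spliced_cds(fix$genome, gm, gid)
    n <- nchar(cds)
    expect_equal(n %% 3L, 0L)
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, n - 2, n) %in% c("TAA", "TAG", "TGA"))
    # translation runs to the terminal stop: no internal stop codon
    expect_equal(nchar(translate_prot <- varaudit:::translate_to_stop(cds)),
                 n / 3 - 1)
  }
  sb <- mean(gm$genes$strand == "+")
  expect_gt(sb, 0.4); expect_lt(sb, 0.6)
  cl <- chrom_lengths_of(fix)
  grw <- gene_rich_windows(gm, cl)
  gaps <- fix$manifest$gaps
  in_gap <- purrr::map_lgl(seq_len(nrow(grw)), function(i) {
    any(gaps$chrom == grw$chrom[i] & gaps$start <= grw$end[i] &
          gaps$end >= grw$start[i] + 1)
  })
  peri <- grw$start >= 2e6 & grw$start < 3e6
  expect_true(all(grw$gene_rich[!peri & !in_gap]))
  expect_true(all(!grw$gene_rich[peri]))
})

test_that("no variant is emitted inside a planted gap run", {
  fix <- fix_density()
  gaps <- fix$manifest$gaps
  for (v in list(fix$lineA, fix$lineB)) {
    hit <- purrr::map_lgl(seq_len(nrow(gaps)), function(i) {
      any(v$chrom == gaps$chrom[i] & v$pos >= gaps$start[i] &
            v$pos <= gaps$end[i])
    })
    expect_false(any(hit))
  }
})

test_that("the expression track closes the loop with the planted maxima", {
  fix <- fix_default()
  expr <- fix$manifest$expression
  set.seed(2)
  ids <- c(fix$manifest$fs$gene_id, sample(expr$gene_id, 80))
  kept <- expression_filter(ids, fix$track, fix$gm, threshold = 200)
  want <- expr$gene_id[expr$gene_id %in% ids & expr$max_value >= 200]
  expect_setequal(kept, want)
  mx <- gene_expression_max(ids, fix$track, fix$gm)
  expect_equal(mx$max_value,
               expr$max_value[match(mx$gene_id, expr$gene_id)])
})

test_that("fixture regeneration from one master seed is identical", {
  f1 <- synth_fixture(77, n_chrom = 1, chrom_length = 2e6, segments = NULL,
                      gap_spec = NULL, with_lineB = FALSE)
  f2 <- synth_fixture(77, n_chrom = 1, chrom_length = 2e6, segments = NULL,
                      gap_spec = NULL, with_lineB = FALSE)
  expect_identical(as.character(f1$genome), as.character(f2$genome))
  expect_identical(f1$lineA, f2$lineA)
  expect_identical(f1$track, f2$track)
  expect_identical(f1$manifest$fs, f2$manifest$fs)
})
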