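test_that("marker selection enforces size bounds, zygosity and region", {
  fix <- fix_default()
  truth <- fix$manifest$markers
  region <- fix$manifest$marker_region
  sel <- select_marker_indels(fix$lineA, region = region)
  expect_equal(nrow(sel), sum(truth$qualifies))
  expect_setequal(sel$pos, truth$pos[truth$qualifies])
  expect_true(all(sel$indel_size >= 10 & sel$indel_size <= 350))
  expect_true(all(sel$genotype == "hom_alt"))
  # the planted 9-bp indels sit just under the floor
  nine <- truth$pos[truth$size == 9]
  expect_false(any(nine %in% sel$pos))
  # lowering the floor admits them
  sel9 <- select_marker_indels(fix$lineA, region = region, min_size = 9)
  expect_true(all(nine %in% sel9$pos))
})

test_that("amplicon sizes differ by exactly the indel length", {
  fix <- fix_default()
  truth <- fix$manifest$markers
  del25 <- truth[truth$size == 25, ][1, ]  # planted as a deletion
  v <- fix$lineA[fix$lineA$pos == del25$pos & fix$lineA$chrom == del25$chrom, ]
  expect_equal(nchar(v$ref) - nchar(v$alt), 25L)
  amp <- design_amplicon(v, fix$genome, target_amplicon = 150)
  expect_equal(amp$expected_size_ref, 150)
  expect_equal(amp$expected_size_alt, 125)
  expect_equal(amp$size_difference, 25)
  ins12 <- truth[truth$size == 12, ][1, ]  # planted as an insertion
  v12 <- fix$lineA[fix$lineA$pos == ins12$pos & fix$lineA$chrom == ins12$chrom, ]
  amp12 <- design_amplicon(v12, fix$genome)
  expect_equal(amp12$expected_size_alt - amp12$expected_size_ref, 12)
  # too close to a contig end is an error
  edge <- v
  edge$pos <- 5L
  edge$ref <- as.character(Biostrings::subseq(fix$genome[[edge$chrom]], 5L, 6L))
  edge$alt <- substr(edge$ref, 1, 1)
  expect_error(design_amplicon(edge, fix$genome), "contig end")
})

test_that("homopolymer and gap-adjacent flanks are flagged", {
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(
    random_seq <- paste(rep(c("A", "C", "G", "T"), 25), collapse = ""),
    strrep("A", 35), "CT",
    paste(rep(c("G", "T", "C", "A"), 40), collapse = ""))))
  pos <- 100 + 35 + 1  # the C after the A-run; left flank is nearly all A
  v <- tibble::tibble(chrom = "chr1", pos = pos,
                      ref = as.character(Biostrings::subseq(g[[1]], pos, pos + 12L)),
                      alt = as.character(Biostrings::subseq(g[[1]], pos, pos)))
  amp <- design_amplicon(v, g, target_amplicon = 80, flank_min = 30)
  expect_equal(amp$flank_quality, "low_complexity")
  gN <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("ACGT", 25), strrep("N", 10),
    strrep("GTCA", 40))))
  vN <- tibble::tibble(chrom = "chr1", pos = 120L,
                       ref = as.character(Biostrings::subseq(gN[[1]], 120L, 132L)),
                       alt = as.character(Biostrings::subseq(gN[[1]], 120L, 120L)))
  ampN <- design_amplicon(vN, gN, target_amplicon = 80, flank_min = 30)
  expect_equal(ampN$flank_quality, "near_gap")
})

test_that("gel resolvability needs 10 bp difference under 500 bp products", {
  expect_true(gel_resolvable(150, 130))
  expect_false(gel_resolvable(150, 145))
  expect_false(gel_resolvable(600, 560))
  expect_true(gel_resolvable(500, 490))
})

test_that("every emitted marker candidate is gel-resolvable", {
  fix <- fix_default()
  norm <- normalize_variants(fix$lineA, fix$genome)
  mt <- marker_table(norm, fix$genome,
                     region = fix$manifest$marker_region)
  expect_gt(nrow(mt), 0)
  expect_true(all(mt$size_difference >= 10))
  expect_true(all(gel_resolvable(mt$expected_size_ref, mt$expected_size_alt)))
  expect_true(all(abs(mt$expected_size_alt - mt$expected_size_ref) ==
                    abs(nchar(mt$alt) - nchar(mt$ref))))
})
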