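test_that("VCF records are parsed, split and genotyped per alt allele", {
  p <- write_test_vcf(tempfile(fileext = ".vcf"), c(
    "chr1\t100\t.\tA\tT\t.\t.\tDP=40;QD=20\tGT\t1/1",
    "chr1\t200\t.\tAT\tA,ATT\t.\t.\tDP=30\tGT\t1/2",
    "chr1\t300\t.\tG\tC\t.\t.\t.\tGT\t./.",
    "chr1\t400\t.\tG\tA\t.\t.\t.\tGT\t0/1"
  ))
  v <- read_variants(p)
  expect_equal(nrow(v), 5L)  # multi-allelic site split into two records
  expect_equal(v$var_class, c("snp", "deletion", "insertion", "snp", "snp"))
  expect_equal(v$genotype, c("hom_alt", "het", "het", "missing", "het"))
  expect_equal(v$dp[1:3], c(40, 30, 30))  # site annotations inherited
  expect_true(all(diff(v$pos) >= 0))
  # splitting conserves the total alt-allele count
  expect_equal(nrow(v[v$pos == 200, ]), 2L)
})

test_that("a missing sample is a hard error naming the available samples", {
  p <- write_test_vcf(tempfile(fileext = ".vcf"),
                      "chr1\t100\t.\tA\tT\t.\t.\t.\tGT\t1/1", sample = "lineX")
  expect_error(read_variants(p, sample = "nope"), "lineX")
})

test_that("allele classification trims before classing", {
  expect_equal(
    classify_alleles(c("A", "AT", "A", "ATG", "CAG"),
                     c("T", "A", "ATT", "CTG", "CAG_wrong" = "CTA")),
    c("snp", "deletion", "insertion", "snp", "mnp_other")
  )
})

test_that("hard filters fail exactly the thresholds crossed", {
  th <- filter_thresholds()
  r <- apply_hard_filters(variant_row(dp = 101, qd = 20, fs = 5, mq = 55), th)
  expect_false(r$filter_pass)
  expect_equal(r$failed_filters[[1]], "max_depth")
  r <- apply_hard_filters(variant_row(qd = 1.9, fs = 61), th)
  expect_equal(sort(r$failed_filters[[1]]), c("max_fisher_strand", "min_qd"))
  # absent annotations pass vacuously
  r <- apply_hard_filters(variant_row(), th)
  expect_true(r$filter_pass)
  expect_length(r$failed_filters[[1]], 0L)
  r <- apply_hard_filters(variant_row(rprs = -8.5, mqrs = -13), th)
  expect_equal(sort(r$failed_filters[[1]]),
               c("min_mq_rank_sum", "min_read_pos_rank_sum"))
})

test_that("relaxing any threshold never turns a pass into a fail", {
  set.seed(42)
  recs <- dplyr::bind_rows(lapply(1:40, function(i) {
    variant_row(dp = sample(50:150, 1), qd = runif(1, 0, 5),
                fs = runif(1, 40, 80), mq = runif(1, 20, 60),
                rprs = runif(1, -12, 0), mqrs = runif(1, -16, 0))
  }))
  strict <- apply_hard_filters(recs, filter_thresholds())
  relaxed <- apply_hard_filters(recs, filter_thresholds(
    max_depth = 120, min_qd = 1, max_fisher_strand = 70, min_mq = 30,
    min_read_pos_rank_sum = -10, min_mq_rank_sum = -14))
  expect_true(all(!strict$filter_pass | relaxed$filter_pass))
})

test_that("homozygous-alt screening flags het and missing genotypes", {
  v <- variant_row(); v$genotype <- "hom_alt"
  expect_true(is_homozygous_alt(v))
  v$genotype <- "het"
  expect_false(is_homozygous_alt(v))
  v$genotype <- "missing"
  expect_warning(res <- is_homozygous_alt(v), "missing")
  expect_false(res)
})

test_that("indel normalization left-aligns homopolymer edits and is idempotent", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "GGCAAATGGTTT"))
  # deletion of one A written at the third A of the AAA run (pos 5, CA->C)
  v <- tibble::tibble(chrom = "chr1", pos = 5L, ref = "AA", alt = "A",
                      genotype = "hom_alt", var_class = "deletion")
  n1 <- normalize_variants(v, genome)
  expect_equal(n1$pos, 3L)  # anchored at the C before the run
  expect_equal(n1$ref, "CA")
  expect_equal(n1$alt, "C")
  n2 <- normalize_variants(n1, genome)
  expect_equal(n1[, c("pos", "ref", "alt")], n2[, c("pos", "ref", "alt")])
  # raw and normalized representations edit the chromosome identically
  s <- as.character(genome[[1]])
  expect_identical(ora_apply_edit(s, v$pos, v$ref, v$alt),
                   ora_apply_edit(s, n1$pos, n1$ref, n1$alt))
  # a reference mismatch is a corrupt-input error
  bad <- v; bad$ref <- "TT"
  expect_error(normalize_variants(bad, genome), "mismatch")
})

test_that("written VCFs round-trip through the reader with FILTER names", {
  fix <- fix_default()
  v <- head(fix$lineA, 200)
  v <- apply_hard_filters(v, filter_thresholds())
  p <- tempfile(fileext = ".vcf")
  write_vcf(v, p, "lineA", chrom_lengths_of(fix))
  back <- read_variants(p)
  expect_equal(nrow(back), nrow(v))
  expect_equal(back$ref, v$ref)
  expect_equal(back$alt, v$alt)
  expect_equal(back$genotype, v$genotype)
  body <- readLines(p)
  body <- body[!startsWith(body, "#")]
  filt <- vapply(strsplit(body, "\t"), `[[`, "", 7L)
  expect_equal(filt == "PASS", v$filter_pass)
})
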