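test_that("candidate pairing takes the union of frame rule and annotation tag", {
  fix <- fix_default()
  norm <- normalize_variants(fix$lineA, fix$genome)
  cand <- fs_candidates(norm, fix$gm)
  fs <- fix$manifest$fs
  # every planted candidate is found, paired with its planted gene
  planted <- dplyr::transmute(fs, chrom, pos, ref, alt, genotype,
                              var_class = classify_alleles(ref, alt))
  norm_fs <- normalize_variants(planted, fix$genome)
  expect_true(all(paste(norm_fs$chrom, norm_fs$pos, fs$gene_id) %in%
                    paste(cand$chrom, cand$pos, cand$gene_id)))
  expect_equal(nrow(cand), nrow(fs))  # background never leaks into the audit
  # an in-frame deletion with no annotation tag is not a candidate
  cd <- fix$gm$cds[fix$gm$cds$gene_id == fs$gene_id[1], ][1, ]
  p <- cd$start + 10L
  v3 <- tibble::tibble(
    chrom = cd$chrom, pos = p,
    ref = as.character(Biostrings::subseq(fix$genome[[cd$chrom]], p, p + 3L)),
    alt = as.character(Biostrings::subseq(fix$genome[[cd$chrom]], p, p)),
    genotype = "hom_alt", var_class = "deletion", ann = NA_character_)
  expect_equal(nrow(fs_candidates(v3, fix$gm)), 0L)
})

test_that("expression filter keeps genes at or above the detectability floor", {
  fix <- fix_default()
  ids <- head(fix$gm$genes$gene_id, 4)
  ex <- fix$gm$exons[fix$gm$exons$gene_id %in% ids, ]
  maxima <- c(0, 150, 200, 5000)
  track <- dplyr::transmute(
    ex, chrom, start, end,
    value = maxima[match(gene_id, ids)])
  mx <- gene_expression_max(ids, track, fix$gm)
  expect_equal(mx$max_value[match(ids, mx$gene_id)], maxima)
  kept <- expression_filter(ids, track, fix$gm, threshold = 200)
  expect_setequal(kept, ids[maxima >= 200])
  # a gene absent from the track is treated as silent, with a warning
  expect_warning(
    none <- expression_filter(fix$gm$genes$gene_id[5], track, fix$gm),
    "absent")
  expect_length(none, 0L)
})

test_that("mutant proteins match the brute-force oracle on planted edits", {
  fix <- fix_default()
  fs <- fix$manifest$fs
  genuine <- fs[fs$truth_verdict == "genuine_fs" & fs$genotype == "hom_alt" &
                  fs$expressed, ]
  for (i in seq_len(nrow(genuine))) {
    v <- genuine[i, c("chrom", "pos", "ref", "alt")]
    nv <- normalize_variants(
      dplyr::mutate(v, genotype = "hom_alt",
                    var_class = classify_alleles(ref, alt)), fix$genome)
    mp <- mutant_protein(nv, fix$gm, genuine$gene_id[i], fix$genome)
    op <- ora_proteins(fix$genome, fix$gm, genuine$gene_id[i], nv)
    expect_identical(mp$ref_prot, op$ref)
    expect_identical(mp$mut_prot, op$mut)
    expect_false(identical(mp$ref_prot, mp$mut_prot))
  }
  # a variant outside every exon leaves the protein untouched
  g <- fix$gm$genes[1, ]
  v <- tibble::tibble(chrom = g$chrom, pos = g$end + 500L,
                      ref = as.character(Biostrings::subseq(
                        fix$genome[[g$chrom]], g$end + 500L, g$end + 501L)),
                      alt = as.character(Biostrings::subseq(
                        fix$genome[[g$chrom]], g$end + 500L, g$end + 500L)))
  mp <- mutant_protein(v, fix$gm, g$gene_id, fix$genome)
  expect_identical(mp$ref_prot, mp$mut_prot)
})

test_that("pseudo-frameshift detection reproduces every planted category", {
  fix <- fix_default()
  fs <- fix$manifest$fs
  for (i in seq_len(nrow(fs))) {
    v <- tibble::tibble(chrom = fs$chrom[i], pos = fs$pos[i], ref = fs$ref[i],
                        alt = fs$alt[i], genotype = fs$genotype[i],
                        var_class = classify_alleles(fs$ref[i], fs$alt[i]))
    aud <- detect_pseudo_fs(v, fix$gm, fs$gene_id[i], fix$genome)
    expect_equal(aud$verdict, fs$truth_verdict[i])
    if (!is.na(fs$truth_reason[i])) {
      expect_equal(aud$pseudo_reason, fs$truth_reason[i])
    }
  }
  # an in-frame deletion wholly inside one CDS interval is never genuine
  # by the frame rule alone
  long_cds <- fix$gm$cds[(fix$gm$cds$end - fix$gm$cds$start) > 60, ][1, ]
  p <- long_cds$start + 15L
  v3 <- tibble::tibble(
    chrom = long_cds$chrom, pos = p,
    ref = as.character(Biostrings::subseq(fix$genome[[long_cds$chrom]], p, p + 3L)),
    alt = as.character(Biostrings::subseq(fix$genome[[long_cds$chrom]], p, p)),
    genotype = "hom_alt", var_class = "deletion")
  aud <- detect_pseudo_fs(v3, fix$gm, long_cds$gene_id, fix$genome)
  expect_equal(aud$verdict, "pseudo_fs")
  expect_equal(aud$pseudo_reason, "inframe_after_normalization")
  # incomplete gene models withhold the verdict
  gm2 <- fix$gm
  gm2$genes$complete[gm2$genes$gene_id == long_cds$gene_id] <- FALSE
  aud2 <- detect_pseudo_fs(v3, gm2, long_cds$gene_id, fix$genome)
  expect_true(aud2$withheld)
  expect_true(is.na(aud2$verdict))
})

test_that("protein impact classes follow the terminus conventions", {
  set.seed(11)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K")
  ref <- paste(sample(aa, 400, replace = TRUE), collapse = "")
  flip <- function(s) chartr("ARNDCQEGHILK", "RNDCQEGHILKA", s)
  sub_at <- function(s, at, repl) {
    paste0(substr(s, 1, at - 1), repl, substr(s, at + nchar(repl), nchar(s)))
  }
  expect_equal(classify_protein_impact(ref, substr(ref, 1, 120)),
               "truncated_major")
  alt_c <- paste0(substr(ref, 1, 389), flip(substr(ref, 390, 395)))
  expect_equal(classify_protein_impact(ref, alt_c), "altered_C_terminal")
  ext <- paste0(substr(ref, 1, 389), flip(paste(rep(substr(ref, 1, 61)), collapse = "")))
  expect_equal(nchar(ext), 450)
  expect_equal(classify_protein_impact(ref, ext), "extended_C_terminal")
  alt_n <- sub_at(ref, 1, flip(substr(ref, 1, 8)))
  expect_equal(classify_protein_impact(ref, alt_n), "altered_N_terminal")
  expect_equal(classify_protein_impact(ref, ref), "minimal")
})

test_that("the cascade is deterministic and handles empty input", {
  fix <- fix_default()
  cc1 <- run_cascade(fix$lineA, fix$gm, fix$genome, fix$track)
  cc2 <- run_cascade(fix$lineA, fix$gm, fix$genome, fix$track)
  expect_identical(cc1$counts, cc2$counts)
  expect_identical(cc1$records$verdict, cc2$records$verdict)
  expect_true(all(diff(cc1$counts$count) <= 0))
  empty <- run_cascade(fix$lineA[0, ], fix$gm, fix$genome, fix$track)
  expect_equal(empty$counts$count, rep(0L, 4))
})

test_that("the accession matrix matches on normalized identity, not gene", {
  fix <- fix_default()
  cc <- run_cascade(fix$lineA, fix$gm, fix$genome, fix$track)
  audited <- cc$records[cc$records$terminal_stage == "genuine_fs", ]
  acc <- synth_accessions(17, audited, fix$genome, fix$gm)
  m <- accession_matrix(audited, acc$vcfs, fix$genome)
  for (a in names(acc$vcfs)) {
    expect_equal(m[[a]], acc$truth[[a]])
  }
  # same gene, different indel: no match
  shifted <- audited[1, ]
  shifted$pos <- shifted$pos + 50L
  shifted$ref <- as.character(Biostrings::subseq(
    fix$genome[[shifted$chrom]], shifted$pos, shifted$pos + 1L))
  shifted$alt <- substr(shifted$ref, 1, 1)
  m2 <- accession_matrix(shifted, list(x = audited[1, ]), fix$genome)
  expect_false(m2$x)
  # foreign contigs are an error
  bad <- audited[1, ]; bad$chrom <- "chrX"
  expect_error(accession_matrix(audited, list(x = bad), fix$genome), "contig")
})
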