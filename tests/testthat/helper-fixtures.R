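# Fixtures are generated once per test run and shared across files.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Full default toy study: 3 x 5 Mb, gene-rich arms, planted segments,
# 20-candidate frameshift plan, marker testbed.
fix_default <- function() cached("default", function() synth_fixture(101))

# Dedicated oracle fixture: one chromosome, 208 frameshift candidates
# spanning every pseudo category, no second line.
fix_oracle <- function() {
  cached("oracle", function() {
    synth_fixture(202, n_chrom = 1, segments = NULL,
                  fs_plan = oracle_fs_plan(), with_lineB = FALSE)
  })
}

# Variant-density fixture (no gene models); used for window/segment checks.
fix_density <- function() {
  cached("density", function() synth_fixture(303, with_genes = FALSE))
}

# Small cascade replicate for multi-seed loop-closure runs.
fix_cascade <- function(seed) {
  synth_fixture(seed, n_chrom = 1, segments = NULL, with_lineB = FALSE)
}

chrom_lengths_of <- function(fix) {
  stats::setNames(Biostrings::width(fix$genome), names(fix$genome))
}

# A bare variant tibble with given annotations (for filter tests).
variant_row <- function(dp = NA, qd = NA, fs = NA, mq = NA,
                        rprs = NA, mqrs = NA) {
  tibble::tibble(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                 genotype = "hom_alt", var_class = "snp",
                 dp = dp, qd = qd, fs = fs, mq = mq,
                 read_pos_rank_sum = rprs, mq_rank_sum = mqrs,
                 ann = NA_character_)
}

# Minimal single-sample VCF writer for parser tests (independent of the
# package's own writer).
write_test_vcf <- function(path, body_lines, sample = "s1") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"q\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"),
    body_lines
  ), path)
  path
}
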