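#!/usr/bin/env Rscript
# Hard-filter the raw parental call sets (depth cap plus QD / FS / MQ /
# rank-sum bounds) and flag heterozygous calls, which in inbred parents are
# most plausibly sequencing or mapping artifacts. Writes filtered VCFs and
# a per-line filter summary.

suppressMessages({
  library(optparse)
  library(varaudit)
  library(dplyr)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--fixture", type = "character", default = "results/fixture"),
  make_option("--outdir", type = "character", default = "results")
)))

genome <- read_genome(file.path(opts$fixture, "genome.fa"))
contigs <- stats::setNames(Biostrings::width(genome), names(genome))
th <- filter_thresholds()
summary_rows <- list()
for (line in c("lineA", "lineB")) {
  v <- read_variants(file.path(opts$fixture, paste0(line, ".vcf")))
  v <- apply_hard_filters(v, th)
  hom <- is_homozygous_alt(v)
  write_vcf(v, file.path(opts$outdir, paste0(line, ".filtered.vcf")),
            line, contigs)
  summary_rows[[line]] <- tibble(
    line = line, n_calls = nrow(v), n_pass = sum(v$filter_pass),
    n_het = sum(v$genotype == "het"), n_hom_alt = sum(hom),
    n_snp = sum(v$var_class == "snp"),
    n_indel = sum(v$var_class %in% c("insertion", "deletion"))
  )
  cat(sprintf("%s: %d calls, %d pass filters, %d heterozygous flagged\n",
              line, nrow(v), sum(v$filter_pass), sum(v$genotype == "het")))
}
readr::write_tsv(bind_rows(summary_rows),
                 file.path(opts$outdir, "filter_summary.tsv"))
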