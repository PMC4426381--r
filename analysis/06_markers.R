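#!/usr/bin/env Rscript
# InDel-based PCR size-marker design: homozygous indels of 10-350 bp get a
# ~150 bp amplicon whose two allele products must separate on a 3% agarose
# gel (>= 10 bp difference, products <= 500 bp). Writes the marker table,
# amplicon BED and flank FASTA for external primer design.

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
v <- read_variants(file.path(opts$fixture, "lineA.vcf"))
v <- normalize_variants(v, genome)
mt <- marker_table(v, genome)
readr::write_tsv(select(mt, -flank_left, -flank_right),
                 file.path(opts$outdir, "markers.tsv"))
bed <- transmute(mt, chrom, start = amp_start - 1L, end = amp_end,
                 name = sprintf("%s_%d_%dbp", chrom, pos, size_difference))
readr::write_tsv(bed, file.path(opts$outdir, "marker_amplicons.bed"),
                 col_names = FALSE)
flanks <- Biostrings::DNAStringSet(c(
  stats::setNames(mt$flank_left, paste0(bed$name, "_left")),
  stats::setNames(mt$flank_right, paste0(bed$name, "_right"))))
Biostrings::writeXStringSet(flanks, file.path(opts$outdir, "marker_flanks.fa"))
cat(sprintf("%d gel-resolvable markers (size differences %d-%d bp, %d flagged flanks)\n",
            nrow(mt), min(mt$size_difference), max(mt$size_difference),
            sum(mt$flank_quality != "ok")))
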