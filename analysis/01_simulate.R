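#!/usr/bin/env Rscript
# Simulate the toy two-parent resequencing study: a 3 x 5 Mb reference with
# pericentromeric assembly gaps, gene-rich euchromatic arms, a low-divergence
# parent (~1 change / 1,100 bp) and a high-divergence parent (~1 change /
# 111 bp), four planted introgression-pattern segments, a 20-candidate
# frameshift plan, and a marker-grade indel testbed. Writes the fixture and
# its truth manifest for the downstream analyses.

suppressMessages({
  library(optparse)
  library(varaudit)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 101L),
  make_option("--outdir", type = "character", default = "results/fixture")
)))

fix <- synth_fixture(opts$seed)
write_fixture(fix, opts$outdir)

cat(sprintf("reference: %d chromosomes, %s bp total, %d gap runs\n",
            length(fix$genome), format(sum(Biostrings::width(fix$genome)),
                                       big.mark = ","), nrow(fix$gaps)))
cat(sprintf("gene models: %d genes (%.0f%% plus strand)\n",
            nrow(fix$gm$genes), 100 * mean(fix$gm$genes$strand == "+")))
cat(sprintf("lineA calls: %s   lineB calls: %s\n",
            format(nrow(fix$lineA), big.mark = ","),
            format(nrow(fix$lineB), big.mark = ",")))
cat(sprintf("planted: %d segments, %d frameshift candidates, %d marker indels\n",
            nrow(fix$manifest$segments), nrow(fix$manifest$fs),
            nrow(fix$manifest$markers)))
cat("fixture written to", opts$outdir, "\n")
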