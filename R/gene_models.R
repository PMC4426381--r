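#' Gene model container
#'
#' A light container for stranded gene models with ordered exon and CDS
#' intervals, as parsed from GFF3. All coordinates are 1-based closed
#' (GFF3/VCF convention). CDS intervals are stored in genomic order; for
#' minus-strand genes transcription order is the reverse.
#'
#' @param genes tibble with columns `gene_id`, `chrom`, `strand` (`+`/`-`),
#'   `start`, `end`, `complete` (logical: start codon at spliced CDS begin
#'   and stop codon at its end).
#' @param exons tibble with `gene_id`, `chrom`, `start`, `end`.
#' @param cds tibble with `gene_id`, `chrom`, `start`, `end`, `phase`.
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, exons, cds) {
  genes <- as_tibble(genes)
  exons <- arrange(as_tibble(exons), .data$gene_id, .data$start)
  cds <- arrange(as_tibble(cds), .data$gene_id, .data$start)
  stopifnot(all(genes$strand %in% c("+", "-")),
            all(exons$end >= exons$start), all(cds$end >= cds$start))
  if (!"complete" %in% names(genes)) genes$complete <- TRUE
  structure(list(genes = genes, exons = exons, cds = cds),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes, %d exons, %d CDS intervals on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons), nrow(x$cds),
              length(unique(x$genes$chrom))))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Expects `gene`, `mRNA`, `exon` and `CDS` features with `ID`/`Parent`
#' attributes; exon and CDS parents are resolved through their mRNA to the
#' gene. Only the first mRNA per gene is retained (the fixtures emit one).
#'
#' @param path GFF3 file.
#' @return A [gene_models] object.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  df$parent <- vapply(df$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                      character(1))
  genes_df <- filter(df, .data$type == "gene")
  mrna <- filter(df, .data$type == "mRNA")
  mrna2gene <- stats::setNames(mrna$parent, mrna$ID)
  feat <- filter(df, .data$type %in% c("exon", "CDS")) |>
    mutate(gene_id = unname(mrna2gene[.data$parent]))
  genes <- tibble(
    gene_id = as.character(genes_df$ID),
    chrom = as.character(genes_df$seqnames),
    strand = as.character(genes_df$strand),
    start = genes_df$start, end = genes_df$end,
    complete = TRUE
  )
  exons <- feat |> filter(.data$type == "exon") |>
    transmute(gene_id = .data$gene_id, chrom = as.character(.data$seqnames),
              start = .data$start, end = .data$end)
  cds <- feat |> filter(.data$type == "CDS") |>
    transmute(gene_id = .data$gene_id, chrom = as.character(.data$seqnames),
              start = .data$start, end = .data$end,
              phase = as.integer(as.character(.data$phase)))
  gene_models(genes, exons, cds)
}

#' Write gene models to GFF3
#'
#' @param gm A [gene_models] object.
#' @param path Output file.
#' @export
write_gff3 <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(gm$genes))) {
    g <- gm$genes[i, ]
    ex <- filter(gm$exons, .data$gene_id == g$gene_id)
    cd <- filter(gm$cds, .data$gene_id == g$gene_id)
    mrna_id <- paste0(g$gene_id, ".1")
    lines <- c(
      sprintf("%s\tvaraudit\tgene\t%d\t%d\t.\t%s\t.\tID=%s", g$chrom, g$start,
              g$end, g$strand, g$gene_id),
      sprintf("%s\tvaraudit\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s", g$chrom,
              g$start, g$end, g$strand, mrna_id, g$gene_id),
      sprintf("%s\tvaraudit\texon\t%d\t%d\t.\t%s\t.\tParent=%s", ex$chrom,
              ex$start, ex$end, g$strand, mrna_id),
      sprintf("%s\tvaraudit\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
              cd$chrom, cd$start, cd$end, g$strand, cd$phase, g$gene_id, mrna_id)
    )
    writeLines(lines, con)
  }
  invisible(path)
}

# CDS intervals of one gene, in genomic order, as a tibble.
gene_cds <- function(gm, gene_id) {
  filter(gm$cds, .data$gene_id == !!gene_id)
}

gene_row <- function(gm, gene_id) {
  g <- filter(gm$genes, .data$gene_id == !!gene_id)
  if (nrow(g) == 0L) abort(sprintf("unknown gene '%s'", gene_id))
  g[1L, ]
}

#' Extract the spliced CDS of a gene
#'
#' Concatenates the CDS intervals in genomic order and reverse-complements
#' for minus-strand genes, yielding the translatable coding sequence.
#'
#' @param genome Named `DNAStringSet` (or list of `DNAString`) keyed by chromosome.
#' @param gm A [gene_models] object.
#' @param gene_id Gene identifier.
#' @return Character scalar: the spliced CDS (5' to 3' of the mRNA).
#' @export
spliced_cds <- function(genome, gm, gene_id) {
  g <- gene_row(gm, gene_id)
  cd <- gene_cds(gm, gene_id)
  if (nrow(cd) == 0L) return("")
  chrom_seq <- genome[[g$chrom]]
  pieces <- vapply(seq_len(nrow(cd)), function(i) {
    as.character(Biostrings::subseq(chrom_seq, cd$start[i], cd$end[i]))
  }, character(1))
  s <- paste(pieces, collapse = "")
  if (g$strand == "-") s <- revcomp_chr(s)
  s
}
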