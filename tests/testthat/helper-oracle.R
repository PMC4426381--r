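# Brute-force oracle, written independently of the package code paths:
# plain-string chromosome editing, arithmetic boundary projection, and a
# codon-by-codon translation loop.

ora_apply_edit <- function(chrom_str, pos, ref, alt) {
  stopifnot(substr(chrom_str, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(chrom_str, 1L, pos - 1L), alt,
         substr(chrom_str, pos + nchar(ref), nchar(chrom_str)))
}

ora_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

ora_translate <- function(s) {
  gc <- Biostrings::GENETIC_CODE
  out <- character(0)
  i <- 1L
  while (i + 2L <= nchar(s)) {
    aa <- gc[[substr(s, i, i + 2L)]]
    if (is.null(aa) || is.na(aa)) aa <- "X"
    if (aa == "*") break
    out <- c(out, aa)
    i <- i + 3L
  }
  paste(out, collapse = "")
}

# Project one boundary coordinate through an anchored edit.
ora_project_point <- function(x, pos, lr, la, is_start) {
  span_end <- pos + lr - 1L
  if (is_start) {
    if (x <= pos) x else if (x > span_end) x + (la - lr) else pos + la
  } else {
    if (x < pos) x
    else if (x > span_end) x + (la - lr)
    else if (x == pos) pos
    else pos + la - 1L
  }
}

# Reference and mutant protein for one (normalized) variant and gene,
# computed from scratch on plain strings.
ora_proteins <- function(genome, gm, gene_id, nv) {
  g <- gm$genes[gm$genes$gene_id == gene_id, ]
  cd <- gm$cds[gm$cds$gene_id == gene_id, ]
  cd <- cd[order(cd$start), ]
  chrom_str <- as.character(genome[[g$chrom]])
  splice <- function(s, starts, ends) {
    paste(substring(s, starts, ends), collapse = "")
  }
  ref_cds <- splice(chrom_str, cd$start, cd$end)
  edited <- ora_apply_edit(chrom_str, nv$pos, nv$ref, nv$alt)
  lr <- nchar(nv$ref); la <- nchar(nv$alt)
  ns <- mapply(function(s, e) {
    c(ora_project_point(s, nv$pos, lr, la, TRUE),
      ora_project_point(e, nv$pos, lr, la, FALSE))
  }, cd$start, cd$end)
  keep <- ns[2, ] >= ns[1, ]
  mut_cds <- splice(edited, ns[1, keep], ns[2, keep])
  if (g$strand == "-") {
    ref_cds <- ora_revcomp(ref_cds)
    mut_cds <- ora_revcomp(mut_cds)
  }
  list(ref = ora_translate(ref_cds), mut = ora_translate(mut_cds))
}

# Oracle verdict: a candidate is a genuine frameshift iff the edited,
# re-spliced, re-translated protein differs from the reference protein.
ora_verdict <- function(genome, gm, gene_id, nv) {
  p <- ora_proteins(genome, gm, gene_id, nv)
  if (identical(p$ref, p$mut)) "pseudo_fs" else "genuine_fs"
}
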