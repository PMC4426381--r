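#' @importFrom rlang .data abort warn %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# Translate a nucleotide sequence up to (not including) the first stop codon.
# Trailing bases that do not fill a codon are ignored; unknown codons give X.
# Uses the standard genetic code (Biostrings::GENETIC_CODE) via a direct
# lookup, which keeps the audit loops fast.
translate_to_stop <- function(seq) {
  s <- as.character(seq)
  n <- nchar(s)
  n3 <- n - n %% 3L
  if (n3 < 3L) return("")
  codons <- substring(s, seq.int(1L, n3 - 2L, 3L), seq.int(3L, n3, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- match("*", aa)
  if (!is.na(stop_at)) aa <- aa[seq_len(stop_at - 1L)]
  paste(aa, collapse = "")
}

# Apply a single anchored edit (VCF semantics: replace [pos, pos+nchar(ref)-1]
# with alt) to one chromosome. `chrom_seq` is a DNAString.
apply_edit_seq <- function(chrom_seq, pos, ref, alt) {
  lr <- nchar(ref)
  observed <- as.character(Biostrings::subseq(chrom_seq, pos, pos + lr - 1L))
  if (!identical(observed, ref)) {
    abort(sprintf(
      "reference allele mismatch at position %d: VCF says '%s', genome has '%s'",
      pos, ref, observed
    ))
  }
  Biostrings::replaceAt(chrom_seq, IRanges::IRanges(pos, pos + lr - 1L), alt)
}

# Project a 1-based closed interval [s, e] through an anchored edit at `pos`
# replacing `lr` reference bases with `la` alternate bases. Boundaries that
# fall strictly inside the replaced span snap to the nearest surviving base.
# An insertion point sitting exactly at an interval end stays outside the
# interval (inserted bases are not pulled into the feature). Returns
# c(new_s, new_e); new_e < new_s means the interval was destroyed.
project_interval <- function(s, e, pos, lr, la) {
  delta <- la - lr
  span_end <- pos + lr - 1L
  new_s <- if (s <= pos) s else if (s > span_end) s + delta else pos + la
  new_e <- if (e < pos) e else if (e > span_end) e + delta else if (e == pos) pos else pos + la - 1L
  c(new_s, new_e)
}

# Reverse-complement on plain character vectors (ACGTN alphabet).
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
  }, character(1), USE.NAMES = FALSE)
}

stop_codons <- c("TAA", "TAG", "TGA")

# The 61 sense codons (no stops); used when building valid CDS sequences.
sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  cod <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(cod, stop_codons)
}
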