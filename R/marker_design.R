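#' Select InDels usable as PCR size markers
#'
#' Keeps normalized indels whose length change lies in
#' `[min_size, max_size]`, optionally restricted to homozygous calls and to
#' a genomic region; results are sorted by position. The 10-bp default floor
#' mirrors the smallest size difference resolvable on a 3% agarose gel.
#'
#' @param variants Normalized variant tibble.
#' @param region Optional list/tibble with `chrom`, `start`, `end` (1-based
#'   closed).
#' @param min_size,max_size Bounds on `abs(nchar(alt) - nchar(ref))`.
#' @param require_hom Keep homozygous-alt calls only (default TRUE).
#' @return Filtered variant tibble with an `indel_size` column.
#' @export
select_marker_indels <- function(variants, region = NULL, min_size = 10,
                                 max_size = 350, require_hom = TRUE) {
  v <- filter(variants, .data$var_class %in% c("insertion", "deletion"))
  v$indel_size <- abs(nchar(v$alt) - nchar(v$ref))
  v <- filter(v, .data$indel_size >= min_size, .data$indel_size <= max_size)
  if (require_hom) v <- filter(v, .data$genotype == "hom_alt")
  if (!is.null(region)) {
    v <- filter(v, .data$chrom == region$chrom, .data$pos >= region$start,
                .data$pos <= region$end)
  }
  arrange(v, .data$chrom, .data$pos)
}

#' Design a size-marker amplicon around an indel
#'
#' Centers an amplicon of approximately `target_amplicon` bp on the indel
#' footprint and reports the expected product sizes on the reference and
#' alternate alleles (differing by the signed indel length). Flanks that are
#' more than 80% a single nucleotide are flagged `low_complexity`; flanks
#' containing N are flagged `near_gap`.
#'
#' @param variant One-row normalized variant tibble.
#' @param genome Named `DNAStringSet`.
#' @param target_amplicon Desired reference product size (default 150 bp).
#' @param flank_min Minimum flank length; indels closer than this to a
#'   contig end are an error.
#' @return One-row tibble: amplicon bounds, `expected_size_ref`,
#'   `expected_size_alt`, `size_difference`, `flank_quality`, and the two
#'   flank sequences (for external primer design).
#' @export
design_amplicon <- function(variant, genome, target_amplicon = 150,
                            flank_min = 30) {
  chrom_seq <- genome[[variant$chrom]]
  clen <- length(chrom_seq)
  lr <- nchar(variant$ref); la <- nchar(variant$alt)
  foot_lo <- variant$pos; foot_hi <- variant$pos + lr - 1L
  left <- max(flank_min, floor((target_amplicon - lr) / 2))
  right <- max(flank_min, target_amplicon - lr - left)
  lo <- foot_lo - left
  hi <- foot_hi + right
  if (foot_lo - flank_min < 1L || foot_hi + flank_min > clen) {
    abort(sprintf("indel at %s:%d is within %d bp of a contig end",
                  variant$chrom, variant$pos, flank_min))
  }
  lo <- max(1L, lo); hi <- min(clen, hi)
  left <- as.character(Biostrings::subseq(chrom_seq, lo, foot_lo - 1L))
  right <- as.character(Biostrings::subseq(chrom_seq, foot_hi + 1L, hi))
  qual <- "ok"
  if (grepl("N", left, fixed = TRUE) || grepl("N", right, fixed = TRUE)) {
    qual <- "near_gap"
  } else if (max_base_fraction(left) > 0.8 || max_base_fraction(right) > 0.8) {
    qual <- "low_complexity"
  }
  size_ref <- hi - lo + 1L
  tibble(chrom = variant$chrom, amp_start = lo, amp_end = hi,
         pos = variant$pos, ref = variant$ref, alt = variant$alt,
         expected_size_ref = size_ref,
         expected_size_alt = size_ref + (la - lr),
         size_difference = abs(la - lr),
         flank_quality = qual, flank_left = left, flank_right = right)
}

max_base_fraction <- function(s) {
  if (!nchar(s)) return(0)
  f <- Biostrings::letterFrequency(Biostrings::DNAString(s), c("A", "C", "G", "T"))
  max(f) / nchar(s)
}

#' Are two PCR product sizes distinguishable on a 3% agarose gel?
#'
#' @param size_a,size_b Product sizes in bp.
#' @param min_diff Minimum resolvable size difference (default 10 bp).
#' @param max_product Largest product still resolved at that difference
#'   (default 500 bp).
#' @return Logical.
#' @export
gel_resolvable <- function(size_a, size_b, min_diff = 10, max_product = 500) {
  stopifnot(all(size_a > 0), all(size_b > 0))
  abs(size_a - size_b) >= min_diff & size_a <= max_product & size_b <= max_product
}

#' Build the full marker table for a variant set
#'
#' Selects marker-grade indels, designs an amplicon for each and keeps only
#' markers whose allele products are gel-resolvable under the active
#' settings.
#'
#' @inheritParams select_marker_indels
#' @inheritParams design_amplicon
#' @inheritParams gel_resolvable
#' @return Tibble of marker candidates (see [design_amplicon()]).
#' @export
marker_table <- function(variants, genome, region = NULL, min_size = 10,
                         max_size = 350, require_hom = TRUE,
                         target_amplicon = 150, flank_min = 30,
                         min_diff = 10, max_product = 500) {
  sel <- select_marker_indels(variants, region, min_size, max_size, require_hom)
  if (nrow(sel) > 0L) {
    clen <- stats::setNames(Biostrings::width(genome), names(genome))
    sel <- filter(sel, .data$pos > flank_min,
                  .data$pos + nchar(.data$ref) - 1L + flank_min <=
                    clen[.data$chrom])
  }
  if (nrow(sel) == 0L) return(tibble())
  out <- bind_rows(lapply(seq_len(nrow(sel)), function(i) {
    design_amplicon(sel[i, ], genome, target_amplicon, flank_min)
  }))
  filter(out, gel_resolvable(.data$expected_size_ref, .data$expected_size_alt,
                             min_diff, max_product))
}
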