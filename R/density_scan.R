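#' Fixed-grid window tiling of a chromosome set
#'
#' Windows are anchored at coordinate 0 and tile each chromosome without
#' overlap; the last window may be short. Bounds are reported 0-based
#' half-open.
#'
#' @param chrom_lengths Named integer vector.
#' @param window_size Window width in bp.
#' @return Tibble with `chrom`, `start`, `end`, `window` (0-based index).
#' @export
window_grid <- function(chrom_lengths, window_size) {
  stopifnot(window_size >= 1)
  purrr::map_dfr(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    n <- ceiling(len / window_size)
    tibble(chrom = ch, window = seq_len(n) - 1L) |>
      mutate(start = .data$window * window_size,
             end = pmin(.data$start + window_size, len)) |>
      select("chrom", "start", "end", "window")
  })
}

#' Windowed SNP and InDel counts
#'
#' Assigns every variant to exactly one window by its (normalized) start
#' position and counts SNPs and InDels separately. Window counts conserve
#' totals: summed over windows they equal the number of SNPs / InDels
#' passed in.
#'
#' @param variants Variant tibble.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param window_size Window width in bp (default 1 Mb).
#' @param include_het Count heterozygous/missing-genotype records too
#'   (default TRUE); the frameshift cascade excludes them regardless.
#' @return Tibble with `chrom`, `start`, `end`, `snp_count`, `indel_count`.
#' @export
window_counts <- function(variants, chrom_lengths, window_size = 1e6,
                          include_het = TRUE) {
  stopifnot(window_size >= 1)
  unknown <- setdiff(unique(variants$chrom), names(chrom_lengths))
  if (length(unknown)) {
    abort(sprintf("variants on unknown chromosome(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  if (!include_het) {
    variants <- filter(variants, .data$genotype %in% c("hom_alt", "hom_ref"))
  }
  grid <- window_grid(chrom_lengths, window_size)
  counts <- variants |>
    mutate(window = (.data$pos - 1L) %/% window_size,
           kind = case_when(.data$var_class == "snp" ~ "snp_count",
                            .data$var_class %in% c("insertion", "deletion") ~ "indel_count",
                            TRUE ~ NA_character_)) |>
    filter(!is.na(.data$kind)) |>
    count(.data$chrom, .data$window, .data$kind) |>
    tidyr::pivot_wider(names_from = "kind", values_from = "n", values_fill = 0L)
  out <- left_join(grid, counts, by = c("chrom", "window"))
  for (col in c("snp_count", "indel_count")) {
    if (!col %in% names(out)) out[[col]] <- 0L
    out[[col]][is.na(out[[col]])] <- 0L
  }
  select(out, "chrom", "start", "end", "snp_count", "indel_count")
}

#' Per-chromosome linear densities, relative to the densest chromosome
#'
#' Computes SNPs and InDels per bp for each chromosome and expresses each
#' relative to the chromosome with the maximum linear density (which gets
#' 1.0; ties broken by chromosome order).
#'
#' @inheritParams window_counts
#' @return Tibble with `chrom`, `snp_per_bp`, `indel_per_bp`,
#'   `relative_snp`, `relative_indel`.
#' @export
chromosome_relative_density <- function(variants, chrom_lengths) {
  if (nrow(variants) == 0L) abort("at least one variant is required")
  if (any(chrom_lengths <= 0)) abort("zero-length chromosome")
  per <- variants |>
    count(.data$chrom,
          kind = ifelse(.data$var_class == "snp", "snp",
                        ifelse(.data$var_class %in% c("insertion", "deletion"),
                               "indel", "other"))) |>
    filter(.data$kind != "other") |>
    tidyr::pivot_wider(names_from = "kind", values_from = "n", values_fill = 0L)
  out <- tibble(chrom = names(chrom_lengths), length = as.numeric(chrom_lengths)) |>
    left_join(per, by = "chrom")
  for (col in c("snp", "indel")) {
    if (!col %in% names(out)) out[[col]] <- 0L
    out[[col]][is.na(out[[col]])] <- 0L
  }
  out <- mutate(out,
                snp_per_bp = .data$snp / .data$length,
                indel_per_bp = .data$indel / .data$length,
                relative_snp = if (max(.data$snp_per_bp) > 0)
                  .data$snp_per_bp / max(.data$snp_per_bp) else 0,
                relative_indel = if (max(.data$indel_per_bp) > 0)
                  .data$indel_per_bp / max(.data$indel_per_bp) else 0)
  select(out, "chrom", "snp_per_bp", "indel_per_bp", "relative_snp",
         "relative_indel")
}

#' Gene-rich windows
#'
#' A window qualifies when strictly more than `min_genes` genes *start*
#' within it (start-position membership avoids double counting genes that
#' span a boundary).
#'
#' @param gm A [gene_models] object.
#' @param chrom_lengths Named integer vector.
#' @param window_size Window width (default 0.5 Mb).
#' @param min_genes Strict lower bound on gene starts per window (default 50).
#' @return Tibble of windows with `gene_count` and logical `gene_rich`.
#' @export
gene_rich_windows <- function(gm, chrom_lengths, window_size = 5e5,
                              min_genes = 50) {
  grid <- window_grid(chrom_lengths, window_size)
  counts <- gm$genes |>
    mutate(window = (.data$start - 1L) %/% window_size) |>
    count(.data$chrom, .data$window, name = "gene_count")
  out <- left_join(grid, counts, by = c("chrom", "window"))
  out$gene_count[is.na(out$gene_count)] <- 0L
  mutate(select(out, -"window"), gene_rich = .data$gene_count > min_genes)
}

#' Assembly-gap windows
#'
#' Per-window fraction of N bases; windows above `flag_threshold` are
#' flagged so their zero variant counts are read as assembly gaps, not as
#' conserved sequence.
#'
#' @param genome Named `DNAStringSet`.
#' @param window_size Window width in bp.
#' @param flag_threshold Gap fraction above which a window is flagged.
#' @return Tibble of windows with `gap_fraction` and logical `gap_flagged`.
#' @export
gap_windows <- function(genome, window_size = 1e6, flag_threshold = 0.5) {
  chrom_lengths <- stats::setNames(Biostrings::width(genome), names(genome))
  grid <- window_grid(chrom_lengths, window_size)
  grid$gap_fraction <- vapply(seq_len(nrow(grid)), function(i) {
    sq <- Biostrings::subseq(genome[[grid$chrom[i]]], grid$start[i] + 1L,
                             grid$end[i])
    Biostrings::letterFrequency(sq, "N")[[1]] / (grid$end[i] - grid$start[i])
  }, numeric(1))
  mutate(select(grid, -"window"),
         gap_flagged = .data$gap_fraction > flag_threshold)
}

#' Full per-window statistics table
#'
#' Combines SNP/InDel counts on the main grid with gene counts on the 0.5-Mb
#' subgrid (reported per window as the max of its halves) and the N-base gap
#' fraction.
#'
#' @inheritParams window_counts
#' @param genome Named `DNAStringSet`.
#' @param gm Optional [gene_models] object.
#' @param flag_threshold Gap-flagging threshold.
#' @return Tibble with `chrom`, `start`, `end`, `snp_count`, `indel_count`,
#'   `gene_count_halfMb`, `gap_fraction`, `gap_flagged`.
#' @export
window_stats <- function(variants, genome, gm = NULL, window_size = 1e6,
                         include_het = TRUE, flag_threshold = 0.5) {
  chrom_lengths <- stats::setNames(Biostrings::width(genome), names(genome))
  wc <- window_counts(variants, chrom_lengths, window_size, include_het)
  gw <- gap_windows(genome, window_size, flag_threshold)
  out <- left_join(wc, select(gw, "chrom", "start", "gap_fraction", "gap_flagged"),
                   by = c("chrom", "start"))
  if (!is.null(gm)) {
    half <- gene_rich_windows(gm, chrom_lengths, window_size = window_size / 2)
    half$parent_start <- (half$start %/% window_size) * window_size
    agg <- half |>
      group_by(.data$chrom, start = .data$parent_start) |>
      summarise(gene_count_halfMb = max(.data$gene_count), .groups = "drop")
    out <- left_join(out, agg, by = c("chrom", "start"))
    out$gene_count_halfMb[is.na(out$gene_count_halfMb)] <- 0L
  } else {
    out$gene_count_halfMb <- NA_integer_
  }
  select(out, "chrom", "start", "end", "snp_count", "indel_count",
         "gene_count_halfMb", "gap_fraction", "gap_flagged")
}
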