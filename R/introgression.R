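#' Call high-density segments from windowed counts
#'
#' Windows whose SNP count meets `high_threshold` (expressed in SNPs/Mb and
#' scaled to the window width) seed segments; runs of seeds separated by at
#' most `merge_gap` non-qualifying, non-gap windows are merged into one
#' segment. Gap-flagged windows never seed and always break a merge.
#'
#' @param stats Window statistics from [window_stats()] (one line, one grid).
#' @param high_threshold Seed threshold in SNPs per Mb.
#' @param merge_gap Maximum run of intervening non-qualifying windows to
#'   bridge (default 1).
#' @return Tibble with `chrom`, `start`, `end` (bp, 0-based half-open),
#'   `n_windows`, `mean_snp_per_mb`, and list-column `support` (window
#'   start coordinates).
#' @export
call_dense_segments <- function(stats, high_threshold, merge_gap = 1L) {
  if (!"gap_flagged" %in% names(stats)) stats$gap_flagged <- FALSE
  out <- list()
  for (ch in unique(stats$chrom)) {
    w <- arrange(filter(stats, .data$chrom == ch), .data$start)
    width_mb <- (w$end - w$start) / 1e6
    qual <- !w$gap_flagged & w$snp_count >= high_threshold * width_mb
    seeds <- which(qual)
    if (!length(seeds)) next
    runs <- list(c(seeds[1L], seeds[1L]))
    for (i in seeds[-1L]) {
      last <- runs[[length(runs)]]
      between <- if (i - last[2L] > 1L) seq(last[2L] + 1L, i - 1L) else integer(0)
      if (length(between) <= merge_gap && !any(w$gap_flagged[between])) {
        runs[[length(runs)]][2L] <- i
      } else {
        runs[[length(runs) + 1L]] <- c(i, i)
      }
    }
    for (r in runs) {
      member <- seq(r[1L], r[2L])
      out[[length(out) + 1L]] <- tibble(
        chrom = ch, start = w$start[r[1L]], end = w$end[r[2L]],
        n_windows = length(member),
        mean_snp_per_mb = mean(w$snp_count[member] / width_mb[member]),
        support = list(w$start[member])
      )
    }
  }
  if (!length(out)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  n_windows = integer(), mean_snp_per_mb = numeric(),
                  support = list()))
  }
  bind_rows(out)
}

# Genome-wide background median window count (per Mb), gap windows excluded.
line_background_per_mb <- function(stats) {
  w <- filter(stats, !.data$gap_flagged)
  stats::median(w$snp_count / ((w$end - w$start) / 1e6))
}

mean_per_mb_over <- function(stats, chrom, start, end) {
  w <- filter(stats, .data$chrom == !!chrom, .data$start >= !!start,
              .data$end <= !!end)
  if (nrow(w) == 0L) return(NA_real_)
  mean(w$snp_count / ((w$end - w$start) / 1e6))
}

#' Classify high-density segments into cross-line pattern classes
#'
#' Line A is the low-divergence parent, line B the high-divergence one; both
#' must be scanned on the same window grid. Over the union of the two lines'
#' segment footprints the per-line mean densities are compared against the
#' per-line background medians:
#'
#' * A high, B at/below its genome-wide floor → `reference_from_wild`
#'   (wild-species introgression fixed in the reference lineage);
#' * A high, B elevated well above its background → `reference_divergent`
#'   (reference carries material divergent from both lines);
#' * A high only → `lineA_specific`;
#' * B high only → `lineB_divergent`.
#'
#' For both-high segments the alternative reading — an introgression in one
#' line later transferred to the other — is recorded in a `note` column.
#'
#' @param stats_a,stats_b Window statistics per line ([window_stats()]).
#' @param lineA_high Absolute seed/classification threshold for line A in
#'   SNPs/Mb (default 5000).
#' @param b_high_factor Line B is "elevated" at `b_high_factor` times its
#'   background median (default 2).
#' @param low_factor "Low" means at most `low_factor` times the background
#'   median (default 0.1).
#' @param merge_gap Passed to [call_dense_segments()].
#' @return Tibble of segments with `pattern_class`, per-line mean densities,
#'   `support` windows and `note`.
#' @export
classify_segments <- function(stats_a, stats_b, lineA_high = 5000,
                              b_high_factor = 2, low_factor = 0.1,
                              merge_gap = 1L) {
  key_a <- paste(stats_a$chrom, stats_a$start)
  key_b <- paste(stats_b$chrom, stats_b$start)
  if (!identical(sort(key_a), sort(key_b))) {
    abort("window grids of the two lines do not match")
  }
  bg_b <- line_background_per_mb(stats_b)
  seg_a <- call_dense_segments(stats_a, lineA_high, merge_gap)
  seg_b <- call_dense_segments(stats_b, b_high_factor * bg_b, merge_gap)
  foot <- merge_footprints(bind_rows(
    select(seg_a, "chrom", "start", "end"),
    select(seg_b, "chrom", "start", "end")
  ))
  if (nrow(foot) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  pattern_class = character(), mean_a_per_mb = numeric(),
                  mean_b_per_mb = numeric(), support = list(),
                  note = character()))
  }
  foot$mean_a_per_mb <- purrr::pmap_dbl(foot, function(chrom, start, end, ...) {
    mean_per_mb_over(stats_a, chrom, start, end)
  })
  foot$mean_b_per_mb <- purrr::pmap_dbl(foot[, 1:3], function(chrom, start, end) {
    mean_per_mb_over(stats_b, chrom, start, end)
  })
  a_high <- foot$mean_a_per_mb >= lineA_high
  b_high <- foot$mean_b_per_mb >= b_high_factor * bg_b
  b_low <- foot$mean_b_per_mb <= low_factor * bg_b
  foot$pattern_class <- dplyr::case_when(
    a_high & b_low ~ "reference_from_wild",
    a_high & b_high ~ "reference_divergent",
    a_high ~ "lineA_specific",
    b_high ~ "lineB_divergent",
    TRUE ~ NA_character_
  )
  foot$note <- ifelse(
    !is.na(foot$pattern_class) & foot$pattern_class == "reference_divergent",
    "alternative: introgression in one line transferred to the other", ""
  )
  foot$support <- purrr::pmap(foot[, 1:3], function(chrom, start, end) {
    w <- filter(stats_a, .data$chrom == !!chrom, .data$start >= !!start,
                .data$end <= !!end)
    w$start
  })
  filter(foot, !is.na(.data$pattern_class))
}

# Merge overlapping/adjacent bp intervals per chromosome.
merge_footprints <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  iv <- arrange(iv, .data$chrom, .data$start)
  out <- iv[1, ]
  if (nrow(iv) > 1L) for (i in 2:nrow(iv)) {
    j <- nrow(out)
    if (iv$chrom[i] == out$chrom[j] && iv$start[i] <= out$end[j]) {
      out$end[j] <- max(out$end[j], iv$end[i])
    } else {
      out <- bind_rows(out, iv[i, ])
    }
  }
  out
}

#' Third-line concordance for a classified segment
#'
#' TRUE when the third line is also elevated (window count at or above
#' `high_threshold`, in SNPs/Mb) over at least half of the segment's
#' windows. Recorded as supporting evidence; it never changes the
#' pattern class.
#'
#' @param segment One row of the [classify_segments()] output.
#' @param third_stats Window statistics of the third line on the same grid.
#' @param high_threshold Elevation threshold in SNPs/Mb.
#' @return Logical scalar.
#' @export
third_line_concordance <- function(segment, third_stats, high_threshold = 5000) {
  w <- filter(third_stats, .data$chrom == segment$chrom,
              .data$start >= segment$start, .data$end <= segment$end)
  if (nrow(w) == 0L) abort("third line not scanned on the segment's grid")
  elevated <- w$snp_count >= high_threshold * (w$end - w$start) / 1e6
  mean(elevated) >= 0.5
}
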