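# Deterministic synthetic fixture generator: toy reference genome, gene
# models, expression track, parental VCFs and a truth manifest that predicts
# the expected output of every pipeline stage.

random_dna <- function(n) {
  if (n <= 0L) return("")
  rawToChar(as.raw(c(65L, 67L, 71L, 84L))[sample.int(4L, n, replace = TRUE)])
}

#' Default assembly-gap specification for the toy genome
#'
#' One 0.7-Mb pericentromeric N-run on chr1 (flagging its 1-Mb window and
#' so separating the two chr1 segment plantings) and one 1.6-Mb run on chr2
#' spanning parts of two 1-Mb windows; chr3 is gap-free.
#' @param n_chrom Number of chromosomes.
#' @return Tibble with `chrom`, `start`, `end` (1-based closed).
#' @export
default_gap_spec <- function(n_chrom = 3) {
  spec <- tibble(chrom = c("chr1", "chr2"),
                 start = c(2200001L, 2400001L),
                 end = c(2900000L, 4000000L))
  filter(spec, .data$chrom %in% paste0("chr", seq_len(n_chrom)))
}

#' Generate the toy reference genome
#'
#' Uniform-random sequence (equal base probabilities) with planted N-runs;
#' byte-identical regeneration from the same seed.
#'
#' @param seed Integer seed.
#' @param n_chrom Number of chromosomes (default 3).
#' @param chrom_length Length of each chromosome in bp (default 5 Mb).
#' @param gap_spec Tibble of N-runs ([default_gap_spec()]); NULL for none.
#' @return List: `genome` (named `DNAStringSet`), `gaps` (tibble).
#' @export
generate_genome <- function(seed, n_chrom = 3, chrom_length = 5e6,
                            gap_spec = default_gap_spec(n_chrom)) {
  stopifnot(chrom_length >= 1e6)
  set.seed(seed)
  if (is.null(gap_spec)) gap_spec <- tibble(chrom = character(), start = integer(),
                                            end = integer())
  if (nrow(gap_spec) && any(gap_spec$end - gap_spec$start + 1L > chrom_length)) {
    abort("gap run longer than chromosome")
  }
  chroms <- paste0("chr", seq_len(n_chrom))
  seqs <- vapply(chroms, function(ch) {
    s <- random_dna(chrom_length)
    for (i in which(gap_spec$chrom == ch)) {
      substr(s, gap_spec$start[i], gap_spec$end[i]) <-
        strrep("N", gap_spec$end[i] - gap_spec$start[i] + 1L)
    }
    s
  }, character(1))
  list(genome = Biostrings::DNAStringSet(stats::setNames(seqs, chroms)),
       gaps = gap_spec)
}

# Build one gene in local plus-orientation coordinates, then flip if needed.
# Returns NULL if it does not fit in `max_len`.
build_gene <- function(gene_id, chrom, genome_start, max_len, strand) {
  sense <- sense_codons()
  n_ex <- sample.int(3L, 1L)
  aa <- sample(80:260, 1L)
  codons <- c("ATG", sense[sample.int(61L, aa, replace = TRUE)],
              stop_codons[sample.int(3L, 1L)])
  coding <- paste(codons, collapse = "")
  clen <- nchar(coding)
  # split coding sequence into n_ex pieces of >= 30 nt
  if (n_ex > 1L) {
    repeat {
      cuts <- sort(sample(seq(30L, clen - 30L), n_ex - 1L))
      if (all(diff(c(0L, cuts, clen)) >= 30L)) break
    }
    piece_len <- diff(c(0L, cuts, clen))
  } else piece_len <- clen
  utr5 <- sample(20:60, 1L); utr3 <- sample(20:60, 1L)
  intron_len <- if (n_ex > 1L) sample(60:140, n_ex - 1L, replace = TRUE) else integer(0)
  total <- utr5 + clen + sum(intron_len) + utr3
  if (total > max_len) return(NULL)

  parts <- character(0); cursor <- 0L
  exon_lo <- integer(n_ex); exon_hi <- integer(n_ex)
  cds_lo <- integer(n_ex); cds_hi <- integer(n_ex)
  off <- 0L  # consumed coding bases
  for (j in seq_len(n_ex)) {
    ex_start <- cursor + 1L
    if (j == 1L) { parts <- c(parts, random_dna(utr5)); cursor <- cursor + utr5 }
    cds_lo[j] <- cursor + 1L
    parts <- c(parts, substr(coding, off + 1L, off + piece_len[j]))
    cursor <- cursor + piece_len[j]; off <- off + piece_len[j]
    cds_hi[j] <- cursor
    if (j == n_ex) { parts <- c(parts, random_dna(utr3)); cursor <- cursor + utr3 }
    exon_lo[j] <- ex_start; exon_hi[j] <- cursor
    if (j < n_ex) {
      parts <- c(parts, paste0("GT", random_dna(intron_len[j] - 4L), "AG"))
      cursor <- cursor + intron_len[j]
    }
  }
  seq <- paste(parts, collapse = "")
  phase <- (3L - cumsum(c(0L, piece_len[-n_ex])) %% 3L) %% 3L
  if (strand == "-") {
    seq <- revcomp_chr(seq)
    flip <- function(lo, hi) list(lo = total - hi + 1L, hi = total - lo + 1L)
    fe <- flip(exon_lo, exon_hi); fc <- flip(cds_lo, cds_hi)
    ord <- rev(seq_len(n_ex))
    exon_lo <- fe$lo[ord]; exon_hi <- fe$hi[ord]
    cds_lo <- fc$lo[ord]; cds_hi <- fc$hi[ord]
    phase <- rev(phase)  # genomic order; transcription order is reversed
  }
  g0 <- genome_start - 1L
  list(seq = seq, start = genome_start, end = g0 + total, strand = strand,
       exon_lo = g0 + exon_lo, exon_hi = g0 + exon_hi,
       cds_lo = g0 + cds_lo, cds_hi = g0 + cds_hi, phase = phase)
}

#' Generate gene models and write them into the genome
#'
#' Multi-exon genes with valid start/stop codons on both strands, placed on
#' a regular slot grid: dense on the euchromatic arms, sparse in the
#' pericentromeric middle (so arm 0.5-Mb windows exceed the gene-rich
#' threshold and pericentromeric ones do not). Gene sequences replace the
#' random background in place, so the returned genome is the one the models
#' describe.
#'
#' @param seed Integer seed.
#' @param genome Named `DNAStringSet` from [generate_genome()].
#' @param gaps Gap tibble; gene slots overlapping a gap are skipped.
#' @param arm_density,peri_density Genes per 0.5-Mb window.
#' @param peri_start,peri_end Pericentromere bounds (0-based half-open, per
#'   chromosome).
#' @return List: `genome` (with genes written in), `gm` ([gene_models]).
#' @export
generate_gene_models <- function(seed, genome, gaps = NULL, arm_density = 120,
                                 peri_density = 5, peri_start = 2e6,
                                 peri_end = 3e6) {
  set.seed(seed)
  if (is.null(gaps)) gaps <- tibble(chrom = character(), start = integer(),
                                    end = integer())
  half <- 5e5
  genes <- list(); exons <- list(); cds <- list()
  out_genome <- genome
  for (ch in names(genome)) {
    clen <- length(genome[[ch]])
    gch <- filter(gaps, .data$chrom == ch)
    repl_at <- integer(0); repl_end <- integer(0); repl_seq <- character(0)
    n_win <- floor(clen / half)
    gidx <- 0L
    for (w in seq_len(n_win) - 1L) {
      win_start <- w * half
      density <- if (win_start >= peri_start && win_start < peri_end)
        peri_density else arm_density
      if (density < 1) next
      slot_w <- floor(half / density)
      if (slot_w < 1500L) abort("gene density infeasible for slot width")
      for (k in seq_len(density) - 1L) {
        slot_lo <- win_start + k * slot_w + 1L
        slot_hi <- slot_lo + slot_w - 1L
        if (slot_hi > clen) next
        if (nrow(gch) && any(gch$start <= slot_hi + 10L & gch$end >= slot_lo - 10L)) next
        gidx <- gidx + 1L
        gid <- sprintf("%s_g%05d", ch, gidx)
        strand <- if (stats::runif(1) < 0.5) "+" else "-"
        gstart <- slot_lo + sample(0:150, 1L)
        g <- build_gene(gid, ch, gstart, slot_hi - gstart + 1L, strand)
        if (is.null(g)) { gidx <- gidx - 1L; next }
        genes[[length(genes) + 1L]] <- list(
          gene_id = gid, chrom = ch, strand = strand, start = g$start,
          end = g$end, complete = TRUE)
        exons[[length(exons) + 1L]] <- list(
          gene_id = gid, chrom = ch, lo = g$exon_lo, hi = g$exon_hi)
        cds[[length(cds) + 1L]] <- list(
          gene_id = gid, chrom = ch, lo = g$cds_lo, hi = g$cds_hi,
          phase = g$phase)
        repl_at <- c(repl_at, g$start); repl_end <- c(repl_end, g$end)
        repl_seq <- c(repl_seq, g$seq)
      }
    }
    if (length(repl_at)) {
      out_genome[[ch]] <- Biostrings::replaceAt(
        genome[[ch]], IRanges::IRanges(repl_at, repl_end),
        Biostrings::DNAStringSet(repl_seq)
      )
    }
  }
  genes_tbl <- tibble(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    chrom = vapply(genes, `[[`, "", "chrom"),
    strand = vapply(genes, `[[`, "", "strand"),
    start = as.integer(vapply(genes, `[[`, 0, "start")),
    end = as.integer(vapply(genes, `[[`, 0, "end")),
    complete = TRUE
  )
  flat <- function(xs, field, idfield = "gene_id") {
    n <- vapply(xs, function(x) length(x$lo), 0L)
    tibble(gene_id = rep(vapply(xs, `[[`, "", idfield), n),
           chrom = rep(vapply(xs, `[[`, "", "chrom"), n),
           start = unlist(lapply(xs, `[[`, "lo"), use.names = FALSE),
           end = unlist(lapply(xs, `[[`, "hi"), use.names = FALSE))
  }
  exons_tbl <- flat(exons)
  cds_tbl <- flat(cds)
  cds_tbl$phase <- unlist(lapply(cds, `[[`, "phase"), use.names = FALSE)
  gm <- gene_models(genes_tbl, exons_tbl, cds_tbl)
  list(genome = out_genome, gm = gm)
}

#' Default planted introgression segments
#'
#' One segment per pattern class, aligned to the 1-Mb window grid and clear
#' of the default gap runs. Densities are planted SNPs/Mb per line (line A
#' is the low-divergence parent).
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `pattern_class`, `density_a`, `density_b`.
#' @export
default_segments <- function() {
  tibble(
    chrom = c("chr1", "chr1", "chr2", "chr3"),
    start = c(0L, 3000000L, 0L, 3000000L),
    end = c(2000000L, 5000000L, 2000000L, 5000000L),
    pattern_class = c("lineB_divergent", "reference_divergent",
                      "lineA_specific", "reference_from_wild"),
    density_a = c(900, 10000, 6000, 6000),
    density_b = c(30000, 20000, 9000, 50)
  )
}

# ---- position sampling over masked genomes --------------------------------

# Allowed IRanges on [1, chrom_len] minus the given exclusion tibble rows.
allowed_ranges <- function(chrom_len, excl) {
  full <- IRanges::IRanges(1L, chrom_len)
  if (is.null(excl) || nrow(excl) == 0L) return(full)
  IRanges::setdiff(full, IRanges::reduce(IRanges::IRanges(excl$start, excl$end)))
}

# n distinct positions uniform over an IRanges mask (without replacement).
sample_positions <- function(n, mask) {
  w <- IRanges::width(mask)
  total <- sum(w)
  if (n > total) n <- total
  if (n <= 0L) return(integer(0))
  u <- sort(sample.int(total, n))
  cw <- cumsum(w)
  block <- findInterval(u - 1L, cw) + 1L
  IRanges::start(mask)[block] + (u - c(0L, cw)[block]) - 1L
}

clip_ranges <- function(mask, lo, hi) {
  IRanges::restrict(mask, as.integer(lo), as.integer(hi))
}

# Nominal passing site annotations.
draw_annotations <- function(n) {
  tibble(
    dp = pmax(8L, round(stats::rnorm(n, 30, 6))),
    qd = round(stats::runif(n, 10, 30), 2),
    fs = round(stats::runif(n, 0, 10), 2),
    mq = round(stats::runif(n, 50, 60), 2),
    read_pos_rank_sum = round(stats::rnorm(n, 0, 1), 3),
    mq_rank_sum = round(stats::rnorm(n, 0, 1), 3)
  )
}

base_at <- function(chrom_seq, pos, width = 1L) {
  if (!length(pos)) return(character(0))
  as.character(Biostrings::extractAt(chrom_seq,
                                     IRanges::IRanges(pos, pos + width - 1L)))
}

make_snp_records <- function(chrom_seq, chrom, pos) {
  ref <- base_at(chrom_seq, pos)
  shift <- sample.int(3L, length(pos), replace = TRUE)
  bases <- c("A", "C", "G", "T")
  alt <- bases[(match(ref, bases) - 1L + shift) %% 4L + 1L]
  tibble(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

make_indel_records <- function(chrom_seq, chrom, pos, max_len = 326L,
                               geom_prob = 0.35) {
  n <- length(pos)
  if (!n) return(tibble(chrom = character(), pos = integer(),
                        ref = character(), alt = character()))
  len <- pmin(stats::rgeom(n, geom_prob) + 1L, max_len)
  is_del <- stats::runif(n) < 0.5
  ref <- character(n); alt <- character(n)
  anchor <- base_at(chrom_seq, pos)
  del <- which(is_del & pos + len < length(chrom_seq))
  ins <- setdiff(seq_len(n), del)
  if (length(del)) {
    ref[del] <- as.character(Biostrings::extractAt(
      chrom_seq, IRanges::IRanges(pos[del], pos[del] + len[del])))
    alt[del] <- anchor[del]
  }
  if (length(ins)) {
    ref[ins] <- anchor[ins]
    # one pooled random string sliced into the per-insertion payloads
    payload <- random_dna(sum(len[ins]))
    stops <- cumsum(len[ins])
    alt[ins] <- paste0(anchor[ins],
                       substring(payload, c(1L, stops[-length(stops)] + 1L), stops))
  }
  keep <- !grepl("N", ref, fixed = TRUE)
  tibble(chrom = chrom, pos = pos, ref = ref, alt = alt)[keep, ]
}
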