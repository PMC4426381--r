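#' Frameshift candidate (variant, gene) pairs
#'
#' A pair qualifies when the variant is an indel whose (normalized) footprint
#' intersects a CDS interval and whose length change is not a multiple of 3,
#' or when the record carries an upstream effect-prediction "frameshift" tag
#' (`ANN` INFO field); the union of both routes is taken, so mis-called
#' annotations enter the audit and can be exposed as pseudo frameshifts.
#'
#' @param variants Normalized variant tibble ([normalize_variants()]).
#' @param gm A [gene_models] object.
#' @return Tibble: the variant columns plus `gene_id` and `route`
#'   (`footprint`, `ann` or `both`).
#' @export
fs_candidates <- function(variants, gm) {
  idx_indel <- which(variants$var_class %in% c("insertion", "deletion"))
  pairs <- list()

  # footprint route: anchor-inclusive footprint overlaps a CDS interval
  if (length(idx_indel)) {
    v <- variants[idx_indel, ]
    frame_shifting <- abs(nchar(v$alt) - nchar(v$ref)) %% 3L != 0L
    for (ch in unique(v$chrom)) {
      vi <- which(v$chrom == ch & frame_shifting)
      cd <- filter(gm$cds, .data$chrom == ch)
      if (!length(vi) || nrow(cd) == 0L) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(v$pos[vi], v$pos[vi] + nchar(v$ref[vi]) - 1L),
        IRanges::IRanges(cd$start, cd$end)
      )
      if (length(hits)) {
        pairs[[length(pairs) + 1L]] <- tibble(
          row = idx_indel[vi][S4Vectors::queryHits(hits)],
          gene_id = cd$gene_id[S4Vectors::subjectHits(hits)],
          route = "footprint"
        )
      }
    }
  }

  # annotation route: emulated effect-prediction frameshift tag
  if (!is.null(variants$ann)) {
    tagged <- which(!is.na(variants$ann) & grepl("frameshift", variants$ann) &
                      variants$var_class %in% c("insertion", "deletion"))
    if (length(tagged)) {
      gid <- vapply(strsplit(variants$ann[tagged], "|", fixed = TRUE),
                    function(p) if (length(p) >= 4L) p[4L] else NA_character_,
                    character(1))
      keep <- !is.na(gid) & gid %in% gm$genes$gene_id
      if (any(keep)) {
        gchrom <- gm$genes$chrom[match(gid[keep], gm$genes$gene_id)]
        same <- gchrom == variants$chrom[tagged[keep]]
        if (any(!same)) {
          warn(sprintf("%d annotated pair(s) skipped: gene on a different chromosome",
                       sum(!same)))
        }
        pairs[[length(pairs) + 1L]] <- tibble(
          row = tagged[keep][same], gene_id = gid[keep][same], route = "ann"
        )
      }
    }
  }

  if (!length(pairs)) {
    out <- variants[integer(0), ]
    out$gene_id <- character(0)
    out$route <- character(0)
    return(out)
  }
  pr <- bind_rows(pairs) |>
    group_by(.data$row, .data$gene_id) |>
    summarise(route = if (n() > 1L) "both" else .data$route[1L], .groups = "drop")
  out <- variants[pr$row, ]
  out$gene_id <- pr$gene_id
  out$route <- pr$route
  arrange(out, .data$chrom, .data$pos, .data$gene_id)
}

#' Per-gene maximum coverage from an expression track
#'
#' @param gene_ids Genes to evaluate.
#' @param track Coverage tibble from [read_bedgraph()].
#' @param gm A [gene_models] object.
#' @return Tibble with `gene_id`, `max_value` (0 with a warning for genes
#'   absent from the track).
#' @export
gene_expression_max <- function(gene_ids, track, gm) {
  out <- tibble(gene_id = unique(gene_ids), max_value = 0)
  missing_genes <- character(0)
  for (i in seq_len(nrow(out))) {
    ex <- filter(gm$exons, .data$gene_id == out$gene_id[i])
    if (nrow(ex) == 0L) { missing_genes <- c(missing_genes, out$gene_id[i]); next }
    tr <- filter(track, .data$chrom == ex$chrom[1L])
    hits <- IRanges::findOverlaps(IRanges::IRanges(ex$start, ex$end),
                                  IRanges::IRanges(tr$start, tr$end))
    vals <- tr$value[S4Vectors::subjectHits(hits)]
    if (!length(vals)) missing_genes <- c(missing_genes, out$gene_id[i])
    else out$max_value[i] <- max(vals)
  }
  if (length(missing_genes)) {
    warn(sprintf("%d gene(s) absent from the expression track treated as 0",
                 length(missing_genes)))
  }
  out
}

#' Expression filter
#'
#' Keeps genes whose maximum coverage over their exons is at or above
#' `threshold`; maxima below it are classed "nondetectable" and dropped
#' (the `< 200` rule, so exactly 200 is kept).
#'
#' @inheritParams gene_expression_max
#' @param threshold Minimum detectable maximum coverage (default 200).
#' @return Character vector: the expressed subset of `gene_ids`.
#' @export
expression_filter <- function(gene_ids, track, gm, threshold = 200) {
  mx <- gene_expression_max(gene_ids, track, gm)
  mx$gene_id[mx$max_value >= threshold]
}

# Deleted genomic span of an anchored edit ([lo, hi], empty for insertions);
# and whether the insertion point falls strictly inside an interval set.
deleted_span <- function(pos, ref, alt) {
  lr <- nchar(ref)
  if (lr > 1L) c(pos + 1L, pos + lr - 1L) else NULL
}

#' Reference and mutant protein for a candidate frameshift
#'
#' Applies the edit to the chromosome, projects the gene's CDS intervals
#' through the edit, re-extracts the spliced CDS (strand-aware) and
#' translates both sequences to the first stop codon. If the edit destroys
#' a splice donor/acceptor dinucleotide the naive projected translation is
#' still returned, with `splice_disrupted = TRUE`.
#'
#' @param variant One-row variant tibble (normalized).
#' @param gm A [gene_models] object.
#' @param gene_id Gene to translate.
#' @param genome Named `DNAStringSet`.
#' @return List with `ref_prot`, `mut_prot`, `splice_disrupted`.
#' @export
mutant_protein <- function(variant, gm, gene_id, genome) {
  g <- gene_row(gm, gene_id)
  cd <- gene_cds(gm, gene_id)
  chrom_seq <- genome[[g$chrom]]
  ref_prot <- translate_to_stop(spliced_cds(genome, gm, gene_id))
  pos <- variant$pos; ref <- variant$ref; alt <- variant$alt
  lr <- nchar(ref); la <- nchar(alt)

  splice_disrupted <- FALSE
  if (nrow(cd) > 1L) {
    dinucs <- rbind(
      cbind(cd$end[-nrow(cd)] + 1L, cd$end[-nrow(cd)] + 2L),   # donor side
      cbind(cd$start[-1L] - 2L, cd$start[-1L] - 1L)            # acceptor side
    )
    ds <- deleted_span(pos, ref, alt)
    for (k in seq_len(nrow(dinucs))) {
      lo <- dinucs[k, 1L]; hi <- dinucs[k, 2L]
      if (!is.null(ds) && ds[1L] <= hi && ds[2L] >= lo) splice_disrupted <- TRUE
      if (la > lr && pos >= lo && pos <= hi - 1L) splice_disrupted <- TRUE
    }
  }

  if (identical(ref, alt) || variant$chrom != g$chrom) {
    return(list(ref_prot = ref_prot, mut_prot = ref_prot,
                splice_disrupted = FALSE))
  }
  edited <- apply_edit_seq(chrom_seq, pos, ref, alt)
  pieces <- character(0)
  for (i in seq_len(nrow(cd))) {
    pr <- project_interval(cd$start[i], cd$end[i], pos, lr, la)
    if (pr[2L] >= pr[1L]) {
      pieces <- c(pieces, as.character(Biostrings::subseq(edited, pr[1L], pr[2L])))
    }
  }
  mut_cds <- paste(pieces, collapse = "")
  if (g$strand == "-") mut_cds <- revcomp_chr(mut_cds)
  list(ref_prot = ref_prot, mut_prot = translate_to_stop(mut_cds),
       splice_disrupted = splice_disrupted)
}

# Does the edit's changed material touch a splice junction or the
# start/stop codon? Junctions are the internal CDS-interval boundaries;
# start/stop codons are the first/last three spliced-CDS bases.
edit_at_border <- function(pos, ref, alt, cd, strand) {
  lr <- nchar(ref); la <- nchar(alt)
  ds <- deleted_span(pos, ref, alt)
  total <- sum(cd$end - cd$start + 1L)
  # genomic intervals of the first and last three spliced-CDS bases
  codon_iv <- function(from_end) {
    want <- 3L; ivs <- list()
    rows <- if (from_end) rev(seq_len(nrow(cd))) else seq_len(nrow(cd))
    for (i in rows) {
      w <- min(want, cd$end[i] - cd$start[i] + 1L)
      ivs[[length(ivs) + 1L]] <- if (from_end) c(cd$end[i] - w + 1L, cd$end[i])
      else c(cd$start[i], cd$start[i] + w - 1L)
      want <- want - w
      if (want == 0L) break
    }
    ivs
  }
  first3 <- codon_iv(strand == "-")
  last3 <- codon_iv(strand != "-")
  touches <- function(lo, hi) {
    if (!is.null(ds) && ds[1L] <= hi && ds[2L] >= lo) return(TRUE)
    la > lr && pos >= lo && pos <= hi - 1L  # insertion point strictly inside
  }
  n <- nrow(cd)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      # insertion exactly at the junction, or deletion crossing it
      if (la > lr && (pos == cd$end[i] || pos == cd$start[i + 1L] - 1L)) return(TRUE)
      if (!is.null(ds) && ds[1L] <= cd$start[i + 1L] && ds[2L] >= cd$end[i]) return(TRUE)
      if (!is.null(ds) && (ds[1L] == cd$start[i + 1L] || ds[2L] == cd$end[i])) return(TRUE)
    }
  }
  for (iv in c(first3, last3)) if (touches(iv[1L], iv[2L])) return(TRUE)
  FALSE
}

#' Audit one candidate frameshift: genuine or pseudo?
#'
#' The variant is re-normalized, then judged in order:
#'
#' 1. `outside_cds_after_normalization` — the normalized footprint no longer
#'    intersects any CDS interval;
#' 2. `inframe_after_normalization` — the net CDS length change (counting
#'    only the portion of the edit inside CDS) is a nonzero multiple of 3;
#' 3. otherwise the mutant protein is computed ([mutant_protein()]); if it
#'    equals the reference the call is pseudo (`border_artifact` when the
#'    changed bases touch a splice junction or start/stop codon,
#'    `protein_unchanged` otherwise); if the proteins differ the frameshift
#'    is `genuine_fs`.
#'
#' @inheritParams mutant_protein
#' @return List: `verdict` (`genuine_fs`/`pseudo_fs`/NA when withheld),
#'   `pseudo_reason`, `ref_prot`, `mut_prot`, `splice_disrupted`,
#'   `withheld` (TRUE for incomplete gene models).
#' @export
detect_pseudo_fs <- function(variant, gm, gene_id, genome) {
  g <- gene_row(gm, gene_id)
  if (!isTRUE(g$complete)) {
    return(list(verdict = NA_character_, pseudo_reason = NA_character_,
                ref_prot = NA_character_, mut_prot = NA_character_,
                splice_disrupted = NA, withheld = TRUE))
  }
  variant <- normalize_variants(variant, genome)
  cd <- gene_cds(gm, gene_id)
  pos <- variant$pos; ref <- variant$ref; alt <- variant$alt
  lr <- nchar(ref); la <- nchar(alt)

  res <- function(verdict, reason = NA_character_, mp = NULL) {
    list(verdict = verdict, pseudo_reason = reason,
         ref_prot = if (is.null(mp)) NA_character_ else mp$ref_prot,
         mut_prot = if (is.null(mp)) NA_character_ else mp$mut_prot,
         splice_disrupted = if (is.null(mp)) NA else mp$splice_disrupted,
         withheld = FALSE)
  }

  foot_lo <- pos; foot_hi <- pos + lr - 1L
  if (!any(cd$start <= foot_hi & cd$end >= foot_lo)) {
    return(res("pseudo_fs", "outside_cds_after_normalization"))
  }

  net <- 0L
  if (la > lr) {                     # anchored insertion
    if (any(cd$start <= pos & pos <= cd$end - 1L)) net <- la - lr
  } else if (lr > la) {              # anchored deletion
    ds <- deleted_span(pos, ref, alt)
    ov <- pmin(cd$end, ds[2L]) - pmax(cd$start, ds[1L]) + 1L
    net <- -sum(ov[ov > 0L])
  }
  if (net != 0L && net %% 3L == 0L) {
    return(res("pseudo_fs", "inframe_after_normalization"))
  }

  mp <- mutant_protein(variant, gm, gene_id, genome)
  if (identical(mp$ref_prot, mp$mut_prot)) {
    reason <- if (edit_at_border(pos, ref, alt, cd, g$strand))
      "border_artifact" else "protein_unchanged"
    return(res("pseudo_fs", reason, mp))
  }
  res("genuine_fs", NA_character_, mp)
}

#' Classify the protein impact of a genuine frameshift
#'
#' With `L = nchar(ref_prot)`, `M = nchar(mut_prot)` and `d` the first
#' differing position: `truncated_major` when the mutant keeps less than
#' half the protein; `extended_C_terminal` when the mutant is longer and
#' diverges only within the final quarter; `altered_C_terminal` /
#' `altered_N_terminal` when differences are confined to the respective
#' terminal quarter (the "~25% of changes on the protein ends" convention);
#' everything else is `truncated_major`. Identical proteins return
#' `minimal` (and should have been caught upstream as pseudo).
#'
#' @param ref_prot,mut_prot Amino-acid strings.
#' @param terminus_fraction Fraction of the protein counted as a terminus.
#' @return One of `truncated_major`, `altered_C_terminal`,
#'   `altered_N_terminal`, `extended_C_terminal`, `minimal`.
#' @export
classify_protein_impact <- function(ref_prot, mut_prot,
                                    terminus_fraction = 0.25) {
  stopifnot(nchar(ref_prot) > 0L, nchar(mut_prot) > 0L)
  if (identical(ref_prot, mut_prot)) return("minimal")
  L <- nchar(ref_prot); M <- nchar(mut_prot)
  rv <- strsplit(ref_prot, "")[[1L]]
  mv <- strsplit(mut_prot, "")[[1L]]
  k <- min(L, M)
  diffs <- which(rv[seq_len(k)] != mv[seq_len(k)])
  d <- if (length(diffs)) diffs[1L] else k + 1L
  if (M < 0.5 * L) return("truncated_major")
  if (M > L && d >= (1 - terminus_fraction) * L) return("extended_C_terminal")
  if (d >= (1 - terminus_fraction) * L) return("altered_C_terminal")
  cs <- 0L
  while (cs < k && rv[L - cs] == mv[M - cs]) cs <- cs + 1L
  if (cs >= (1 - terminus_fraction) * L &&
      (L - cs) <= terminus_fraction * L && (M - cs) <= terminus_fraction * L) {
    return("altered_N_terminal")
  }
  "truncated_major"
}

#' Run the full frameshift audit cascade
#'
#' Stages, in order: frameshift candidates → homozygous-only → expressed
#' genes only → pseudo-frameshift screen → protein-impact classification of
#' the genuine survivors. Every candidate appears exactly once in the audit
#' table with its terminal stage recorded; stage counts are non-increasing.
#'
#' @param variants Variant tibble (raw; normalized internally). May also be
#'   a VCF path.
#' @param gm A [gene_models] object or GFF3 path.
#' @param genome Named `DNAStringSet` or FASTA path.
#' @param track Expression tibble ([read_bedgraph()]) or bedGraph path.
#' @param expression_threshold Detectable-expression floor (default 200).
#' @return List with `records` (one row per candidate: stage flags, verdict,
#'   `pseudo_reason`, `impact_class`, `terminal_stage`,
#'   `multi_candidate_gene`) and `counts` (per-stage survivor table).
#' @export
run_cascade <- function(variants, gm, genome, track,
                        expression_threshold = 200) {
  if (is.character(genome)) genome <- read_genome(genome)
  if (is.character(gm)) gm <- read_gff3(gm)
  if (is.character(variants)) variants <- read_variants(variants)
  if (is.character(track)) track <- read_bedgraph(track)

  variants <- normalize_variants(variants, genome)
  cand <- fs_candidates(variants, gm)
  n_cand <- nrow(cand)

  rec <- cand
  rec$is_fs_candidate <- TRUE
  rec$is_homozygous <- if (n_cand) is_homozygous_alt(cand) else logical(0)
  expressed_genes <- if (n_cand) {
    expression_filter(unique(cand$gene_id), track, gm, expression_threshold)
  } else character(0)
  rec$is_expressed <- rec$gene_id %in% expressed_genes

  rec$verdict <- NA_character_
  rec$pseudo_reason <- NA_character_
  rec$impact_class <- NA_character_
  rec$splice_disrupted <- NA
  live <- which(rec$is_homozygous & rec$is_expressed)
  for (i in live) {
    aud <- detect_pseudo_fs(rec[i, ], gm, rec$gene_id[i], genome)
    rec$verdict[i] <- aud$verdict
    rec$pseudo_reason[i] <- aud$pseudo_reason
    rec$splice_disrupted[i] <- aud$splice_disrupted
    if (identical(aud$verdict, "genuine_fs")) {
      rec$impact_class[i] <- classify_protein_impact(aud$ref_prot, aud$mut_prot)
    }
  }
  rec$terminal_stage <- dplyr::case_when(
    !rec$is_homozygous ~ "heterozygous",
    !rec$is_expressed ~ "nondetectable_expression",
    rec$verdict == "pseudo_fs" ~ "pseudo_fs",
    rec$verdict == "genuine_fs" ~ "genuine_fs",
    TRUE ~ "withheld"
  )
  rec$multi_candidate_gene <- rec$gene_id %in%
    rec$gene_id[duplicated(rec$gene_id)]

  counts <- tibble(
    stage = c("candidates", "homozygous", "expressed", "genuine_fs"),
    count = c(n_cand, sum(rec$is_homozygous),
              sum(rec$is_homozygous & rec$is_expressed),
              sum(rec$terminal_stage == "genuine_fs"))
  )
  list(records = rec, counts = counts)
}

#' Cross-accession frameshift sharing matrix
#'
#' For each audited frameshift, tests whether each accession carries a
#' normalized indel identical in (chrom, pos, ref, alt) — identity matching,
#' not gene-level matching.
#'
#' @param audited Audit records (rows of `run_cascade()$records`, or any
#'   variant tibble with a `gene_id` column).
#' @param other_vcfs Named list: accession → VCF path or variant tibble.
#' @param genome Named `DNAStringSet` (for normalizing accession calls).
#' @return Tibble: `gene_id`, `chrom`, `pos`, `ref`, `alt`, then one logical
#'   column per accession.
#' @export
accession_matrix <- function(audited, other_vcfs, genome) {
  out <- select(audited, "gene_id", "chrom", "pos", "ref", "alt")
  for (acc in names(other_vcfs)) {
    v <- other_vcfs[[acc]]
    if (is.character(v)) v <- read_variants(v)
    bad <- setdiff(unique(v$chrom), names(genome))
    if (length(bad)) {
      abort(sprintf("accession '%s' has contigs absent from the reference: %s",
                    acc, paste(bad, collapse = ", ")))
    }
    v <- normalize_variants(v, genome)
    key <- paste(v$chrom, v$pos, v$ref, v$alt)
    out[[acc]] <- paste(out$chrom, out$pos, out$ref, out$alt) %in% key
  }
  out
}
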