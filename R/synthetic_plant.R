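# Planting of frameshift candidates, background variants, introgression
# segments and marker-grade indels, plus fixture orchestration.

#' Default frameshift-candidate plan
#'
#' Twenty candidates: five genuine frameshifts (two early truncations, one
#' C-terminal edit, one extension-seeking insertion, one on a minus-strand
#' gene), six heterozygous artifact candidates, five in silent genes, and
#' one pseudo frameshift of each flavour (left-aligns out of CDS; splice
#' junction insertion; in-frame stop-codon deletion; insertion just after
#' the stop codon).
#' @return Tibble with a `kind` column, one row per candidate.
#' @export
default_fs_plan <- function() {
  tibble(kind = c(rep("genuine_early", 2), "genuine_late", "genuine_extend",
                  "genuine_minus", rep("het_candidate", 6),
                  rep("silent_candidate", 5), "pseudo_outside", "pseudo_border",
                  "pseudo_inframe", "pseudo_after_stop"))
}

#' Large frameshift plan for oracle validation
#'
#' 208 homozygous, expressed candidates spanning every pseudo-frameshift
#' category and genuine frameshifts on both strands.
#' @return Tibble with a `kind` column.
#' @export
oracle_fs_plan <- function() {
  tibble(kind = c(rep("genuine_early", 40), rep("genuine_late", 20),
                  rep("genuine_extend", 12), rep("genuine_minus", 36),
                  rep("pseudo_outside", 25), rep("pseudo_border", 25),
                  rep("pseudo_inframe", 25), rep("pseudo_after_stop", 25)))
}

# Generator-internal truth computation: splice the CDS out of the edited
# gene by direct string surgery (anchored indel semantics), translate, and
# compare with the reference protein. Kept simple and local so manifest
# truth does not depend on the audit code path.
surgery_protein <- function(genome, gm, gene_id, pos, ref, alt) {
  g <- gene_row(gm, gene_id)
  cd <- gene_cds(gm, gene_id)
  lr <- nchar(ref); la <- nchar(alt)
  chrom_seq <- genome[[g$chrom]]
  ref_pieces <- character(nrow(cd)); mut_pieces <- character(nrow(cd))
  for (i in seq_len(nrow(cd))) {
    s <- cd$start[i]; e <- cd$end[i]
    piece <- as.character(Biostrings::subseq(chrom_seq, s, e))
    ref_pieces[i] <- piece
    if (la > lr && pos >= s && pos <= e - 1L) {          # insertion inside
      k <- pos - s + 1L
      piece <- paste0(substr(piece, 1L, k), substr(alt, 2L, la),
                      substr(piece, k + 1L, nchar(piece)))
    } else if (lr > la) {                                 # deletion overlap
      lo <- max(s, pos + 1L); hi <- min(e, pos + lr - 1L)
      if (lo <= hi) {
        piece <- paste0(substr(piece, 1L, lo - s),
                        substr(piece, hi - s + 2L, nchar(piece)))
      }
    }
    mut_pieces[i] <- piece
  }
  ref_cds <- paste(ref_pieces, collapse = "")
  mut_cds <- paste(mut_pieces, collapse = "")
  if (g$strand == "-") {
    ref_cds <- revcomp_chr(ref_cds); mut_cds <- revcomp_chr(mut_cds)
  }
  list(ref_prot = translate_to_stop(ref_cds),
       mut_prot = translate_to_stop(mut_cds))
}

# Genomic position of the k-th spliced-CDS base of a plus-strand gene.
spliced_to_genomic <- function(cd, k) {
  w <- cd$end - cd$start + 1L
  cw <- cumsum(w)
  j <- which(k <= cw)[1L]
  cd$start[j] + (k - c(0L, cw)[j]) - 1L
}

# Check a planted reference CDS is still a clean ORF after a base edit.
valid_orf <- function(genome, gm, gene_id) {
  cds <- spliced_cds(genome, gm, gene_id)
  n <- nchar(cds)
  if (n %% 3L != 0L || substr(cds, 1L, 3L) != "ATG") return(FALSE)
  if (!substr(cds, n - 2L, n) %in% stop_codons) return(FALSE)
  nchar(translate_to_stop(cds)) == n / 3L - 1L
}

# Plant the frameshift-candidate set. Returns the (possibly base-edited)
# genome plus one truth row per candidate. Uses the current RNG stream.
plant_fs <- function(genome, gm, plan, exclude_region = NULL) {
  if (is.null(plan) || nrow(plan) == 0L || nrow(gm$genes) == 0L) {
    return(list(genome = genome, fs = tibble()))
  }
  info <- gm$cds |>
    group_by(.data$gene_id) |>
    summarise(n_cds = dplyr::n(), cds_len = sum(.data$end - .data$start + 1L),
              .groups = "drop") |>
    left_join(gm$genes, by = "gene_id")
  if (!is.null(exclude_region)) {
    info <- filter(info, !(.data$chrom == exclude_region$chrom &
                             .data$start <= exclude_region$end &
                             .data$end >= exclude_region$start))
  }
  info <- filter(info, .data$cds_len >= 450L)
  pool <- info[sample.int(nrow(info)), ]
  ptr <- 0L
  next_gene <- function(pred) {
    while (ptr < nrow(pool)) {
      ptr <<- ptr + 1L
      if (pred(pool[ptr, ])) return(pool[ptr, ])
    }
    abort("gene pool exhausted while planting frameshift candidates")
  }
  b1 <- function(ch, p) as.character(Biostrings::subseq(genome[[ch]], p, p))

  rows <- list()
  exp_pool <- c(200, 5000, 800, 2500, 1200, 600, 3000, 400, 1800, 950)
  sil_pool <- c(0, 50, 150, 199, 100)
  n_exp <- 0L; n_sil <- 0L
  for (kind in plan$kind) {
    genotype <- if (kind == "het_candidate") "het" else "hom_alt"
    expressed <- kind != "silent_candidate"
    if (expressed) {
      n_exp <- n_exp + 1L
      maxv <- exp_pool[(n_exp - 1L) %% length(exp_pool) + 1L]
    } else {
      n_sil <- n_sil + 1L
      maxv <- sil_pool[(n_sil - 1L) %% length(sil_pool) + 1L]
    }
    edit_kind <- switch(kind, het_candidate = "genuine_early",
                        silent_candidate = "genuine_early", kind)
    made <- NULL
    while (is.null(made)) {
      made <- switch(
        edit_kind,
        genuine_early = , genuine_late = {
          g <- next_gene(function(x) x$strand == "+")
          cd <- gene_cds(gm, g$gene_id)
          frac <- if (edit_kind == "genuine_early") stats::runif(1, 0.05, 0.2)
          else stats::runif(1, 0.78, 0.88)
          k <- max(8L, round(frac * g$cds_len))
          p <- spliced_to_genomic(cd, k)
          j <- which(cd$start <= p & cd$end >= p)[1L]
          p <- min(max(p, cd$start[j] + 5L), cd$end[j] - 8L)
          list(gene = g, pos = p, ref = base_at(genome[[g$chrom]], p, 2L),
               alt = b1(g$chrom, p), truth = "surgery")
        },
        genuine_minus = {
          g <- next_gene(function(x) x$strand == "-")
          cd <- gene_cds(gm, g$gene_id)
          j <- which.max(cd$end - cd$start)
          p <- cd$start[j] + sample(5L:(cd$end[j] - cd$start[j] - 8L), 1L)
          list(gene = g, pos = p, ref = base_at(genome[[g$chrom]], p, 2L),
               alt = b1(g$chrom, p), truth = "surgery")
        },
        genuine_extend = {
          g <- next_gene(function(x) x$strand == "+")
          cd <- gene_cds(gm, g$gene_id)
          found <- NULL
          for (frac in c(0.93, 0.9, 0.87, 0.84)) {
            k <- round(frac * g$cds_len)
            p <- spliced_to_genomic(cd, k)
            j <- which(cd$start <= p & cd$end >= p)[1L]
            if (p < cd$start[j] + 2L || p > cd$end[j] - 2L) next
            ref <- b1(g$chrom, p)
            alt <- paste0(ref, strrep("CCA", 11L), "C")  # 34 bp, stop-free
            sp <- surgery_protein(genome, gm, g$gene_id, p, ref, alt)
            if (identical(sp$ref_prot, sp$mut_prot)) next
            cls <- classify_protein_impact(sp$ref_prot, sp$mut_prot)
            found <- list(gene = g, pos = p, ref = ref, alt = alt, truth = "surgery")
            if (cls == "extended_C_terminal") break
          }
          found
        },
        pseudo_outside = {
          g <- next_gene(function(x) x$strand == "+" && x$n_cds >= 2)
          cd <- gene_cds(gm, g$gene_id)
          s <- cd$start[2L]
          old <- base_at(genome[[g$chrom]], s, 2L)
          genome[[g$chrom]] <- Biostrings::replaceAt(
            genome[[g$chrom]], IRanges::IRanges(s, s + 1L),
            Biostrings::DNAStringSet("GG"))
          if (!valid_orf(genome, gm, g$gene_id)) {
            genome[[g$chrom]] <- Biostrings::replaceAt(   # revert, try next gene
              genome[[g$chrom]], IRanges::IRanges(s, s + 1L),
              Biostrings::DNAStringSet(old))
            NULL
          } else {
            # raw right-shifted representation inside the exon; left-aligns
            # to the intron's terminal AG
            list(gene = g, pos = s, ref = "G", alt = "GG",
                 truth = "pseudo", reason = "outside_cds_after_normalization")
          }
        },
        pseudo_border = {
          g <- next_gene(function(x) {
            if (x$strand != "+" || x$n_cds < 2) return(FALSE)
            cd <- gene_cds(gm, x$gene_id)
            b1(x$chrom, cd$end[1L]) != "G"
          })
          cd <- gene_cds(gm, g$gene_id)
          e <- cd$end[1L]
          ref <- b1(g$chrom, e)
          list(gene = g, pos = e, ref = ref, alt = paste0(ref, "G"),
               truth = "pseudo", reason = "border_artifact")
        },
        pseudo_inframe = {
          g <- next_gene(function(x) {
            if (x$strand != "+") return(FALSE)
            cd <- gene_cds(gm, x$gene_id)
            e <- max(cd$end)
            b1(x$chrom, e - 3L) != b1(x$chrom, e)
          })
          cd <- gene_cds(gm, g$gene_id)
          e <- max(cd$end)
          list(gene = g, pos = e - 3L,
               ref = base_at(genome[[g$chrom]], e - 3L, 4L),
               alt = b1(g$chrom, e - 3L),
               truth = "pseudo", reason = "inframe_after_normalization")
        },
        pseudo_after_stop = {
          g <- next_gene(function(x) x$strand == "+")
          cd <- gene_cds(gm, g$gene_id)
          e <- max(cd$end)
          ref <- b1(g$chrom, e)
          list(gene = g, pos = e, ref = ref, alt = paste0(ref, "C"),
               truth = "pseudo", reason = "protein_unchanged")
        },
        abort(sprintf("unknown fs plan kind '%s'", kind))
      )
    }
    g <- made$gene
    if (identical(made$truth, "surgery")) {
      sp <- surgery_protein(genome, gm, g$gene_id, made$pos, made$ref, made$alt)
      if (identical(sp$ref_prot, sp$mut_prot)) {
        verdict <- "pseudo_fs"; reason <- "protein_unchanged"; impact <- NA_character_
      } else {
        verdict <- "genuine_fs"; reason <- NA_character_
        impact <- classify_protein_impact(sp$ref_prot, sp$mut_prot)
      }
    } else {
      verdict <- "pseudo_fs"; reason <- made$reason; impact <- NA_character_
    }
    rows[[length(rows) + 1L]] <- tibble(
      kind = kind, gene_id = g$gene_id, chrom = g$chrom, pos = made$pos,
      ref = made$ref, alt = made$alt, genotype = genotype,
      expressed = expressed, max_value = maxv,
      truth_verdict = verdict, truth_reason = reason, truth_impact = impact
    )
  }
  fs <- bind_rows(rows)
  fs$ann <- sprintf("%s|frameshift_variant|HIGH|%s", fs$alt, fs$gene_id)
  list(genome = genome, fs = fs)
}

#' Default marker-plan region and composition
#'
#' Thirty indels planted in a dedicated arm region: seven marker-grade
#' (homozygous, 10-32 bp), five 9-bp homozygous (just under the gel floor),
#' four heterozygous of marker size, and fourteen small homozygous indels.
#' @return List with `region` (chrom/start/end) and `plan` tibble.
#' @export
default_marker_plan <- function() {
  list(
    region = list(chrom = "chr2", start = 4100000L, end = 4900000L),
    plan = tibble(
      size = c(10L, 12L, 15L, 20L, 25L, 28L, 32L, rep(9L, 5),
               11L, 14L, 18L, 22L, rep(c(1L, 2L, 3L, 4L, 5L, 6L, 8L), 2)),
      genotype = c(rep("hom_alt", 12), rep("het", 4), rep("hom_alt", 14)),
      qualifies = c(rep(TRUE, 7), rep(FALSE, 23))
    )
  )
}

# Background + segment + marker planting for one line.
plant_line <- function(genome, gm, gaps, segments, line_col, rate,
                       indel_frac_arm, indel_frac_peri, het_fraction,
                       peri_start, peri_end, marker = NULL) {
  seg_excl <- if (!is.null(segments) && nrow(segments)) {
    transmute(segments, .data$chrom, start = .data$start + 1L, end = .data$end)
  } else NULL
  cds_pad <- if (nrow(gm$cds)) {
    transmute(gm$cds, .data$chrom, start = pmax(1L, .data$start - 400L),
              end = .data$end + 400L)
  } else NULL
  recs <- list()
  bg_bp <- list()
  for (ch in names(genome)) {
    clen <- length(genome[[ch]])
    excl_common <- bind_rows(
      filter(gaps, .data$chrom == ch),
      if (!is.null(seg_excl)) filter(seg_excl, .data$chrom == ch)
    )
    snp_mask <- allowed_ranges(clen, excl_common)
    indel_excl <- bind_rows(
      excl_common,
      if (!is.null(cds_pad)) filter(cds_pad, .data$chrom == ch),
      if (!is.null(marker)) {
        filter(tibble(chrom = marker$region$chrom,
                      start = marker$region$start,
                      end = marker$region$end), .data$chrom == ch)
      }
    )
    indel_mask <- allowed_ranges(clen, indel_excl)
    zone_iv <- function(starts, ends) {
      keep <- starts <= pmin(ends, clen) & starts <= clen
      IRanges::IRanges(as.integer(starts[keep]),
                       as.integer(pmin(ends, clen)[keep]))
    }
    zones <- list(arm = zone_iv(c(1L, peri_end + 1L), c(peri_start, clen)),
                  peri = zone_iv(peri_start + 1L, peri_end))
    p_ind <- c(arm = indel_frac_arm, peri = indel_frac_peri)
    for (zn in names(zones)) {
      ziv <- zones[[zn]]
      if (length(ziv) == 0L) next
      zw <- sum(IRanges::width(IRanges::intersect(snp_mask, ziv)))
      n_snp <- stats::rpois(1L, rate * (1 - p_ind[[zn]]) * zw)
      n_ind <- stats::rpois(1L, rate * p_ind[[zn]] * zw)
      sp <- sample_positions(n_snp, IRanges::intersect(snp_mask, ziv))
      ip <- sample_positions(n_ind, IRanges::intersect(indel_mask, ziv))
      recs[[length(recs) + 1L]] <- make_snp_records(genome[[ch]], ch, sp)
      recs[[length(recs) + 1L]] <- make_indel_records(genome[[ch]], ch, ip)
    }
    bg_bp[[length(bg_bp) + 1L]] <- tibble(
      chrom = ch, bp = sum(IRanges::width(snp_mask)),
      expected_changes = rate * sum(IRanges::width(snp_mask))
    )
  }
  # segment overlays: planted SNP densities per pattern class
  if (!is.null(segments) && nrow(segments)) {
    dcol <- if (line_col == "A") "density_a" else "density_b"
    for (i in seq_len(nrow(segments))) {
      sg <- segments[i, ]
      mask <- allowed_ranges(length(genome[[sg$chrom]]),
                             filter(gaps, .data$chrom == sg$chrom))
      mask <- clip_ranges(mask, sg$start + 1L, sg$end)
      lambda <- sg[[dcol]] * (sg$end - sg$start) / 1e6
      pos <- sample_positions(stats::rpois(1L, lambda), mask)
      recs[[length(recs) + 1L]] <- make_snp_records(genome[[sg$chrom]], sg$chrom, pos)
    }
  }
  bg <- bind_rows(recs)
  bg$genotype <- sample(c("hom_alt", "het"), nrow(bg), replace = TRUE,
                        prob = c(1 - het_fraction, het_fraction))
  list(records = bg, background = bind_rows(bg_bp))
}

# Marker-grade indels in the dedicated region (line A only).
plant_markers <- function(genome, gm, gaps, marker) {
  region <- marker$region; plan <- marker$plan
  clen <- length(genome[[region$chrom]])
  cds_pad <- filter(gm$cds, .data$chrom == region$chrom) |>
    transmute(chrom = .data$chrom, start = pmax(1L, .data$start - 400L),
              end = .data$end + 400L)
  mask <- allowed_ranges(clen, bind_rows(filter(gaps, .data$chrom == region$chrom),
                                         cds_pad))
  mask <- clip_ranges(mask, region$start + 200L, region$end - 200L)
  if (sum(IRanges::width(mask)) < nrow(plan) * 60L) {
    abort("marker region too constrained to place the planned indels")
  }
  repeat {
    pos <- sort(sample_positions(nrow(plan), mask))
    if (length(pos) == nrow(plan) && all(diff(pos) >= 60L)) break
  }
  ref <- character(nrow(plan)); alt <- character(nrow(plan))
  is_del <- seq_len(nrow(plan)) %% 2L == 1L
  for (i in seq_len(nrow(plan))) {
    anchor <- base_at(genome[[region$chrom]], pos[i])
    if (is_del[i]) {
      ref[i] <- base_at(genome[[region$chrom]], pos[i], plan$size[i] + 1L)
      alt[i] <- anchor
    } else {
      ref[i] <- anchor
      alt[i] <- paste0(anchor, random_dna(plan$size[i]))
    }
  }
  tibble(chrom = region$chrom, pos = pos, ref = ref, alt = alt,
         genotype = plan$genotype, size = plan$size, qualifies = plan$qualifies)
}

#' Plant parental variant calls and the truth manifest
#'
#' Background SNPs/InDels at the per-line rates (InDels enriched on the
#' gene-rich arms and kept out of coding sequence so the audit ground truth
#' is exactly the planted candidate set), introgression-segment overlays,
#' the frameshift-candidate plan (line A), marker-grade indels (line A),
#' and a `het_fraction` of artifact heterozygous calls.
#'
#' @param seed Integer seed (uses its own RNG stream).
#' @param genome Named `DNAStringSet` (as returned by
#'   [generate_gene_models()], i.e. with genes written in).
#' @param gm [gene_models].
#' @param gaps Gap tibble.
#' @param lineA_rate,lineB_rate Sequence changes per bp (defaults 1/1100 and
#'   1/111).
#' @param segments Planted segment tibble ([default_segments()]) or NULL.
#' @param fs_plan Frameshift plan ([default_fs_plan()]) or NULL.
#' @param marker_plan Marker plan ([default_marker_plan()]) or NULL.
#' @param het_fraction Fraction of background calls emitted heterozygous.
#' @param indel_frac_arm,indel_frac_peri Fraction of background changes that
#'   are indels on arms / pericentromere (3x arm enrichment).
#' @param peri_start,peri_end Pericentromere bounds.
#' @param with_lineB Also generate the high-divergence line (FALSE for
#'   audit-only fixtures where only line A matters).
#' @return List: `genome` (possibly base-edited for planted homopolymer
#'   contexts), `lineA`, `lineB` (variant tibbles), `truth` (manifest parts).
#' @export
plant_variants <- function(seed, genome, gm, gaps,
                           lineA_rate = 1 / 1100, lineB_rate = 1 / 111,
                           segments = default_segments(),
                           fs_plan = default_fs_plan(),
                           marker_plan = default_marker_plan(),
                           het_fraction = 0.02,
                           indel_frac_arm = 0.15, indel_frac_peri = 0.05,
                           peri_start = 2e6, peri_end = 3e6,
                           with_lineB = TRUE) {
  set.seed(seed)
  stopifnot(lineA_rate > 0, lineA_rate < 1, lineB_rate > 0, lineB_rate < 1)
  if (!is.null(marker_plan) &&
      !marker_plan$region$chrom %in% names(genome)) {
    marker_plan <- NULL  # marker testbed chromosome absent from this genome
  }
  fsr <- plant_fs(genome, gm, fs_plan,
                  exclude_region = if (!is.null(marker_plan)) marker_plan$region)
  genome <- fsr$genome
  la <- plant_line(genome, gm, gaps, segments, "A", lineA_rate,
                   indel_frac_arm, indel_frac_peri, het_fraction,
                   peri_start, peri_end, marker = marker_plan)
  lb <- if (with_lineB) {
    plant_line(genome, gm, gaps, segments, "B", lineB_rate,
               indel_frac_arm, indel_frac_peri, het_fraction,
               peri_start, peri_end)
  } else {
    list(records = tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          genotype = character()),
         background = tibble(chrom = character(), bp = numeric(),
                             expected_changes = numeric()))
  }
  markers <- if (!is.null(marker_plan)) plant_markers(genome, gm, gaps, marker_plan)

  assemble <- function(parts) {
    parts <- purrr::compact(parts)
    all <- bind_rows(lapply(seq_along(parts), function(i) {
      p <- parts[[i]]
      p$planted <- i < length(parts)  # planted parts come first
      p
    }))
    all <- arrange(all, .data$chrom, .data$pos, dplyr::desc(.data$planted))
    all <- all[!duplicated(all[, c("chrom", "pos")]), ]
    if (!"ann" %in% names(all)) all$ann <- NA_character_
    all$var_class <- classify_alleles(all$ref, all$alt)
    ann_tbl <- draw_annotations(nrow(all))
    bind_cols(select(all, "chrom", "pos", "ref", "alt", "genotype",
                     "var_class", "ann"), ann_tbl) |>
      arrange(.data$chrom, .data$pos)
  }
  fs_rec <- if (nrow(fsr$fs)) {
    select(fsr$fs, "chrom", "pos", "ref", "alt", "genotype", "ann")
  }
  mk_rec <- if (!is.null(markers)) {
    select(markers, "chrom", "pos", "ref", "alt", "genotype")
  }
  lineA <- assemble(list(fs_rec, mk_rec, la$records))
  lineB <- assemble(list(lb$records))

  list(genome = genome, lineA = lineA, lineB = lineB,
       truth = list(
         rates = list(lineA = lineA_rate, lineB = lineB_rate,
                      indel_frac_arm = indel_frac_arm,
                      indel_frac_peri = indel_frac_peri,
                      het_fraction = het_fraction),
         background = bind_rows(mutate(la$background, line = "lineA"),
                                mutate(lb$background, line = "lineB")),
         segments = segments, fs = fsr$fs, markers = markers,
         marker_region = if (!is.null(marker_plan)) marker_plan$region,
         peri = c(start = peri_start, end = peri_end)
       ))
}

#' Generate the expression coverage track
#'
#' Per-gene plateau coverage over exons at the planted maximum (intergenic
#' baseline 0, silent genes emitted at 0 so they are present in the track).
#'
#' @param seed Integer seed.
#' @param gm [gene_models].
#' @param forced Optional tibble `gene_id`, `max_value` overriding the draw
#'   (used for the frameshift-plan genes).
#' @param expressed_fraction Fraction of remaining genes drawn expressed.
#' @return List: `track` (tibble chrom/start/end/value, 1-based closed),
#'   `expression` (tibble gene_id/max_value).
#' @export
generate_expression_track <- function(seed, gm, forced = NULL,
                                      expressed_fraction = 0.6) {
  set.seed(seed)
  expr <- tibble(gene_id = gm$genes$gene_id)
  on_pool <- c(250, 400, 800, 1500, 3000, 5000)
  off_pool <- c(0, 40, 90, 150, 190)
  is_on <- stats::runif(nrow(expr)) < expressed_fraction
  expr$max_value <- ifelse(is_on,
                           on_pool[sample.int(length(on_pool), nrow(expr), TRUE)],
                           off_pool[sample.int(length(off_pool), nrow(expr), TRUE)])
  if (!is.null(forced) && nrow(forced)) {
    hit <- match(forced$gene_id, expr$gene_id)
    expr$max_value[hit[!is.na(hit)]] <- forced$max_value[!is.na(hit)]
  }
  track <- gm$exons |>
    left_join(expr, by = "gene_id") |>
    transmute(.data$chrom, .data$start, .data$end, value = .data$max_value) |>
    arrange(.data$chrom, .data$start)
  list(track = track, expression = expr)
}

#' Generate a complete synthetic fixture
#'
#' Orchestrates genome, gene models, variant planting and expression track
#' under one master seed (each stage on its own derived stream) and returns
#' everything with the truth manifest. `with_genes = FALSE` yields a
#' variant-density-only fixture (no gene models, frameshift plan or
#' markers), used when only the window-level statistics matter.
#'
#' @param seed Master seed.
#' @param n_chrom,chrom_length Genome shape (defaults 3 x 5 Mb).
#' @param with_genes Generate gene models and gene-anchored plantings.
#' @param gap_spec,arm_density,peri_density,segments,fs_plan,marker_plan,het_fraction
#'   Passed through to the stage generators.
#' @param lineA_rate,lineB_rate Background change rates per bp.
#' @param with_lineB Also generate the high-divergence line.
#' @return List: `genome`, `gaps`, `gm`, `lineA`, `lineB`, `track`,
#'   `manifest`.
#' @export
synth_fixture <- function(seed, n_chrom = 3, chrom_length = 5e6,
                          with_genes = TRUE,
                          gap_spec = default_gap_spec(n_chrom),
                          arm_density = 120, peri_density = 5,
                          segments = default_segments(),
                          fs_plan = default_fs_plan(),
                          marker_plan = default_marker_plan(),
                          lineA_rate = 1 / 1100, lineB_rate = 1 / 111,
                          het_fraction = 0.02, with_lineB = TRUE) {
  sub <- function(k) (seed + k * 1000003L) %% 2147483647L
  gg <- generate_genome(sub(0L), n_chrom, chrom_length, gap_spec)
  if (with_genes) {
    gmres <- generate_gene_models(sub(1L), gg$genome, gg$gaps,
                                  arm_density, peri_density)
    genome <- gmres$genome; gm <- gmres$gm
  } else {
    genome <- gg$genome
    gm <- gene_models(
      tibble(gene_id = character(), chrom = character(), strand = character(),
             start = integer(), end = integer(), complete = logical()),
      tibble(gene_id = character(), chrom = character(), start = integer(),
             end = integer()),
      tibble(gene_id = character(), chrom = character(), start = integer(),
             end = integer(), phase = integer())
    )
    fs_plan <- NULL; marker_plan <- NULL
  }
  pv <- plant_variants(sub(2L), genome, gm, gg$gaps,
                       lineA_rate = lineA_rate, lineB_rate = lineB_rate,
                       segments = segments, fs_plan = fs_plan,
                       marker_plan = marker_plan, het_fraction = het_fraction,
                       with_lineB = with_lineB)
  track <- NULL; expression <- NULL
  if (with_genes) {
    forced <- if (nrow(pv$truth$fs)) {
      select(pv$truth$fs, "gene_id", "max_value")
    }
    tr <- generate_expression_track(sub(3L), gm, forced)
    track <- tr$track; expression <- tr$expression
  }
  chrom_lengths <- stats::setNames(Biostrings::width(pv$genome),
                                   names(pv$genome))
  manifest <- c(pv$truth, list(
    seed = seed, chrom_lengths = as.list(chrom_lengths),
    gaps = gg$gaps, expression = expression,
    arm_density = if (with_genes) arm_density else NULL,
    peri_density = if (with_genes) peri_density else NULL
  ))
  list(genome = pv$genome, gaps = gg$gaps, gm = gm, lineA = pv$lineA,
       lineB = pv$lineB, track = track, manifest = manifest)
}

#' Write a fixture to disk
#'
#' Emits FASTA, GFF3, one VCF per line, bedGraph, a gap BED and the manifest
#' as JSON.
#'
#' @param fix A [synth_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  contigs <- stats::setNames(Biostrings::width(fix$genome), names(fix$genome))
  write_genome(fix$genome, file.path(dir, "genome.fa"))
  if (nrow(fix$gm$genes)) write_gff3(fix$gm, file.path(dir, "genes.gff3"))
  write_vcf(fix$lineA, file.path(dir, "lineA.vcf"), "lineA", contigs)
  write_vcf(fix$lineB, file.path(dir, "lineB.vcf"), "lineB", contigs)
  if (!is.null(fix$track)) write_bedgraph(fix$track, file.path(dir, "expression.bedgraph"))
  if (nrow(fix$gaps)) {
    readr::write_tsv(transmute(fix$gaps, .data$chrom, start = .data$start - 1L,
                               .data$end),
                     file.path(dir, "gaps.bed"), col_names = FALSE,
                     progress = FALSE)
  }
  jsonlite::write_json(fix$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Generate accession call sets sharing planted frameshift indels
#'
#' Each accession carries each audited indel with probability `share_prob`
#' (recorded in the returned truth matrix) plus its own background indels
#' away from coding sequence.
#'
#' @param seed Integer seed.
#' @param audited Variant tibble of audited frameshift indels (needs
#'   `chrom`, `pos`, `ref`, `alt`, `gene_id`).
#' @param genome Named `DNAStringSet`.
#' @param gm [gene_models].
#' @param n_accessions Number of accessions.
#' @param share_prob Per-cell sharing probability.
#' @return List: `vcfs` (named list of variant tibbles), `truth` (tibble
#'   gene_id x accession logicals).
#' @export
synth_accessions <- function(seed, audited, genome, gm, n_accessions = 3,
                             share_prob = 0.5) {
  set.seed(seed)
  truth <- select(audited, "gene_id", "chrom", "pos", "ref", "alt")
  vcfs <- list()
  cds_pad <- transmute(gm$cds, .data$chrom, start = pmax(1L, .data$start - 400L),
                       end = .data$end + 400L)
  for (k in seq_len(n_accessions)) {
    acc <- sprintf("acc%02d", k)
    carry <- stats::runif(nrow(audited)) < share_prob
    truth[[acc]] <- carry
    own <- bind_rows(lapply(names(genome), function(ch) {
      mask <- allowed_ranges(length(genome[[ch]]),
                             filter(cds_pad, .data$chrom == ch))
      make_indel_records(genome[[ch]], ch, sample_positions(20L, mask))
    }))
    own$genotype <- "hom_alt"
    shared <- select(audited[carry, ], "chrom", "pos", "ref", "alt")
    shared$genotype <- "hom_alt"
    v <- bind_rows(shared, own)
    v <- v[!duplicated(v[, c("chrom", "pos")]), ]
    v$var_class <- classify_alleles(v$ref, v$alt)
    v$ann <- NA_character_
    v <- bind_cols(v, draw_annotations(nrow(v)))
    vcfs[[acc]] <- arrange(v, .data$chrom, .data$pos)
  }
  list(vcfs = vcfs, truth = truth)
}
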