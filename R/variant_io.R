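#' Classify REF/ALT allele pairs
#'
#' Alleles are trimmed (shared suffix, then shared prefix) before
#' classification: `snp` for single-base substitutions, `insertion` /
#' `deletion` when one trimmed allele is empty, `mnp_other` otherwise.
#'
#' @param ref,alt Character vectors of equal length.
#' @return Character vector over `snp`, `insertion`, `deletion`, `mnp_other`.
#' @export
classify_alleles <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  out <- character(length(ref))
  lr <- nchar(ref); la <- nchar(alt)
  simple_snp <- lr == 1L & la == 1L & ref != alt
  out[simple_snp] <- "snp"
  rest <- which(!simple_snp)
  for (i in rest) {
    tr <- trim_alleles(ref[i], alt[i])
    nr <- nchar(tr[1]); na <- nchar(tr[2])
    out[i] <- if (nr == 1L && na == 1L && tr[1] != tr[2]) "snp"
    else if (nr == 0L && na > 0L) "insertion"
    else if (na == 0L && nr > 0L) "deletion"
    else "mnp_other"
  }
  out
}

# Trim shared suffix then shared prefix; may return empty strings.
trim_alleles <- function(ref, alt) {
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
  }
  c(ref, alt)
}

info_keys <- c(dp = "DP", qd = "QD", fs = "FS", mq = "MQ",
               read_pos_rank_sum = "ReadPosRankSum", mq_rank_sum = "MQRankSum")

#' Read variant calls from a VCF file
#'
#' Reads a VCF 4.x file through vcfR, splits multi-allelic sites into one
#' record per (site, alt allele) — each inheriting the site annotations —
#' and maps the sample genotype onto `hom_ref` / `het` / `hom_alt` /
#' `missing` relative to that alt allele. Records are returned in
#' (chrom, pos) order.
#'
#' @param vcf_path VCF file.
#' @param sample Sample name; may be omitted for single-sample files.
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt`, `genotype`,
#'   `var_class`, the numeric site annotations `dp`, `qd`, `fs`, `mq`,
#'   `read_pos_rank_sum`, `mq_rank_sum`, and the `ann` effect string
#'   (NA when absent).
#' @export
read_variants <- function(vcf_path, sample = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- v@fix
  samples <- colnames(v@gt)[-1L]
  if (is.null(sample)) {
    if (length(samples) != 1L) {
      abort(sprintf("sample must be given; available samples: %s",
                    paste(samples, collapse = ", ")))
    }
    sample <- samples[1L]
  } else if (!sample %in% samples) {
    abort(sprintf("sample '%s' not in VCF; available samples: %s",
                  sample, paste(samples, collapse = ", ")))
  }
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  bad <- which(is.na(pos))
  if (length(bad)) {
    abort(sprintf("malformed VCF record at data line %d: POS '%s'",
                  bad[1L], fix[bad[1L], "POS"]))
  }
  gt <- vcfR::extract.gt(v, element = "GT")[, sample]
  ann <- vcfR::extract.info(v, element = "ANN")
  info <- lapply(info_keys, function(k) {
    suppressWarnings(vcfR::extract.info(v, element = k, as.numeric = TRUE))
  })

  alt_list <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  idx <- rep.int(seq_len(nrow(fix)), n_alt)
  alt_index <- sequence(n_alt)

  geno <- genotype_for_alt(rep.int(unname(gt), n_alt), alt_index)
  out <- tibble(
    chrom = fix[idx, "CHROM"],
    pos = pos[idx],
    ref = fix[idx, "REF"],
    alt = unlist(alt_list, use.names = FALSE),
    genotype = geno
  )
  out$var_class <- classify_alleles(out$ref, out$alt)
  for (nm in names(info_keys)) out[[nm]] <- info[[nm]][idx]
  out$ann <- if (all(is.na(ann))) NA_character_ else unname(ann[idx])
  arrange(out, .data$chrom, .data$pos)
}

# Map diploid GT strings to genotype classes relative to alt allele `k`.
genotype_for_alt <- function(gt, k) {
  alleles <- strsplit(ifelse(is.na(gt), ".", gt), "[/|]")
  vapply(seq_along(alleles), function(i) {
    a <- alleles[[i]]
    if (any(a == ".") || length(a) == 0L) return("missing")
    hits <- sum(a == as.character(k[i]))
    if (hits == length(a)) "hom_alt" else if (hits > 0L) "het" else "hom_ref"
  }, character(1))
}

#' Hard-filter thresholds
#'
#' Site-level hard-filter bounds in the GATK style: depth cap plus floors /
#' ceilings on quality-by-depth, Fisher strand bias, mapping quality and the
#' two rank-sum statistics. The rank-sum bounds are lower bounds at -8 and
#' -12.5, their conventional signs.
#'
#' @param max_depth,min_qd,max_fisher_strand,min_mq,min_read_pos_rank_sum,min_mq_rank_sum
#'   Numeric thresholds.
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(max_depth = 100, min_qd = 2,
                              max_fisher_strand = 60, min_mq = 40,
                              min_read_pos_rank_sum = -8,
                              min_mq_rank_sum = -12.5) {
  th <- list(max_depth = max_depth, min_qd = min_qd,
             max_fisher_strand = max_fisher_strand, min_mq = min_mq,
             min_read_pos_rank_sum = min_read_pos_rank_sum,
             min_mq_rank_sum = min_mq_rank_sum)
  stopifnot(all(vapply(th, is.finite, logical(1))), th$max_depth > 0)
  structure(th, class = "filter_thresholds")
}

#' Apply hard filters to variant records
#'
#' A record fails when DP > max_depth, QD < min_qd, FS > max_fisher_strand,
#' MQ < min_mq, ReadPosRankSum < min_read_pos_rank_sum or MQRankSum <
#' min_mq_rank_sum. Absent annotations pass their filter (the GATK
#' convention for rank-sum fields, applied uniformly).
#'
#' @param variants Variant tibble from [read_variants()].
#' @param th A [filter_thresholds()] object.
#' @return `variants` with logical `filter_pass` and list-column
#'   `failed_filters` (character vector of failed filter names per record).
#' @export
apply_hard_filters <- function(variants, th = filter_thresholds()) {
  fails <- cbind(
    max_depth = !is.na(variants$dp) & variants$dp > th$max_depth,
    min_qd = !is.na(variants$qd) & variants$qd < th$min_qd,
    max_fisher_strand = !is.na(variants$fs) & variants$fs > th$max_fisher_strand,
    min_mq = !is.na(variants$mq) & variants$mq < th$min_mq,
    min_read_pos_rank_sum = !is.na(variants$read_pos_rank_sum) &
      variants$read_pos_rank_sum < th$min_read_pos_rank_sum,
    min_mq_rank_sum = !is.na(variants$mq_rank_sum) &
      variants$mq_rank_sum < th$min_mq_rank_sum
  )
  nm <- colnames(fails)
  variants$failed_filters <- lapply(seq_len(nrow(variants)),
                                    function(i) nm[fails[i, ]])
  variants$filter_pass <- rowSums(fails) == 0L
  variants
}

#' Is a record a homozygous alternate call?
#'
#' Heterozygous calls in inbred parental lines are treated as likely
#' sequencing/mapping artifacts downstream; missing genotypes return FALSE
#' with a warning.
#'
#' @param variants Variant tibble.
#' @return Logical vector.
#' @export
is_homozygous_alt <- function(variants) {
  if (any(variants$genotype == "missing")) {
    warn(sprintf("%d record(s) with missing genotype treated as not homozygous-alt",
                 sum(variants$genotype == "missing")))
  }
  variants$genotype == "hom_alt"
}

# Normalize a single anchored allele pair: trim shared suffix then shared
# prefix (keeping at least one base of each), then left-align while the edit
# stays sequence-equivalent. `chrom_seq` is a DNAString.
normalize_one <- function(chrom_seq, pos, ref, alt) {
  clen <- length(chrom_seq)
  observed <- as.character(Biostrings::subseq(chrom_seq, pos, min(clen, pos + nchar(ref) - 1L)))
  if (!identical(observed, ref)) {
    abort(sprintf("reference mismatch at %d: VCF '%s' vs genome '%s'", pos, ref, observed))
  }
  win_lo <- max(1L, pos - 400L)
  local <- as.character(Biostrings::subseq(chrom_seq, win_lo,
                                           min(clen, pos + nchar(ref) + 4L)))
  off <- pos - win_lo + 1L  # position of `pos` inside `local`
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0L && na > 0L &&
        substr(ref, nr, nr) == substr(alt, na, na) && (nr > 1L || na > 1L)) {
      prev_ref <- ref; prev_alt <- alt
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (pos == 1L) { # cannot extend left past the chromosome start
          ref <- prev_ref; alt <- prev_alt
          break
        }
        pos <- pos - 1L; off <- off - 1L
        if (off < 1L) {
          win_lo <- max(1L, pos - 400L)
          local <- as.character(Biostrings::subseq(chrom_seq, win_lo,
                                                   min(clen, pos + 400L)))
          off <- pos - win_lo + 1L
        }
        b <- substr(local, off, off)
        ref <- paste0(b, ref); alt <- paste0(b, alt)
      }
      next
    }
    break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Left-align and parsimony-normalize indel records
#'
#' SNPs pass through unchanged. For insertions and deletions the shared
#' suffix and prefix are trimmed and the edit is shifted left while it
#' remains sequence-equivalent, so that e.g. an edit inside a homopolymer is
#' reported at the run's first base. Applying the original and the
#' normalized record to the chromosome yields identical sequences;
#' normalization is idempotent.
#'
#' @param variants Variant tibble.
#' @param genome Named `DNAStringSet`.
#' @return The tibble with `pos`, `ref`, `alt`, `var_class` updated.
#' @export
normalize_variants <- function(variants, genome) {
  is_indel <- variants$var_class %in% c("insertion", "deletion")
  idx <- which(is_indel)
  for (i in idx) {
    ch <- variants$chrom[i]
    if (!ch %in% names(genome)) abort(sprintf("unknown chromosome '%s'", ch))
    nrm <- normalize_one(genome[[ch]], variants$pos[i], variants$ref[i], variants$alt[i])
    variants$pos[i] <- nrm$pos
    variants$ref[i] <- nrm$ref
    variants$alt[i] <- nrm$alt
  }
  variants$var_class[idx] <- classify_alleles(variants$ref[idx], variants$alt[idx])
  variants
}

#' Write variant records to a VCF 4.2 file
#'
#' Emits one line per record (multi-allelic sites are not re-merged). When
#' `failed_filters` is present the FILTER column carries the failed filter
#' names (semicolon-joined) or PASS.
#'
#' @param variants Variant tibble.
#' @param path Output file.
#' @param sample_name Sample column name.
#' @param contigs Named integer vector of chromosome lengths.
#' @export
write_vcf <- function(variants, path, sample_name = "sample1", contigs = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(contigs)) sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                                   as.integer(contigs)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Approximate read depth\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Predicted effect\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  n <- nrow(variants)
  fields <- list()
  for (nm in names(info_keys)) {
    val <- variants[[nm]]
    if (is.null(val)) next
    txt <- if (nm == "dp") sprintf("%s=%d", info_keys[[nm]], as.integer(val))
    else sprintf("%s=%g", info_keys[[nm]], val)
    txt[is.na(val)] <- NA_character_
    fields[[nm]] <- txt
  }
  if (!is.null(variants$ann)) {
    fields$ann <- ifelse(is.na(variants$ann), NA_character_,
                         paste0("ANN=", variants$ann))
  }
  info <- if (length(fields)) {
    apply(do.call(cbind, fields), 1L, function(x) {
      x <- x[!is.na(x)]
      if (length(x)) paste(x, collapse = ";") else "."
    })
  } else rep(".", n)
  filt <- if ("failed_filters" %in% names(variants)) {
    vapply(variants$failed_filters, function(f) {
      if (length(f)) paste(f, collapse = ";") else "PASS"
    }, character(1))
  } else rep(".", nrow(variants))
  gtmap <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s\tGT\t%s",
                  variants$chrom, variants$pos, variants$ref, variants$alt,
                  filt, info, gtmap[variants$genotype])
  writeLines(c(hdr, body), path)
  invisible(path)
}
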