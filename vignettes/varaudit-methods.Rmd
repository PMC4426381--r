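---
title: "Auditing parental-line variants: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing parental-line variants: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

When two inbred parental lines of a mapping population are resequenced
against a common reference, four questions follow the variant calls:

1. Which calls survive rule-based quality screening, and which are artifacts
   (in fully inbred material, heterozygous calls are themselves suspect)?
2. How are the surviving SNPs and InDels distributed along the chromosomes —
   and which localized density anomalies mark putative introgressions?
3. Which coding InDels annotated as frameshifts by effect-prediction
   software actually change the protein, once the indel's ambiguous
   placement is resolved?
4. Which InDels make practical PCR size markers for fine mapping?

`varaudit` implements each step as a small set of composable functions over
plain tibbles and Bioconductor containers, plus a deterministic synthetic
study generator whose truth manifest predicts the expected output of every
stage. The numbered scripts under `analysis/` run the whole study end to
end on the synthetic data.

# Hard filtering and genotype semantics

`apply_hard_filters()` implements the conventional site-level hard-filter
rule set: depth above 100 fails, quality-by-depth below 2, Fisher strand
bias above 60, RMS mapping quality below 40, and the two rank-sum
statistics below −8 (read position) and −12.5 (mapping quality). The two
rank-sum bounds are stated as magnitudes in some pipelines; we use the
canonical lower-bound signs, since positive bounds would discard almost
nothing. Records lacking an annotation pass that filter vacuously — the
standard convention for rank-sum fields, which are undefined at
homozygous-reference-free sites. Depth is interpreted as site depth (DP),
not per-sample depth. The filter returns the complete list of failed filter
names so the FILTER column of a written VCF is self-explanatory.

Heterozygous and missing-genotype records are *retained but flagged*:
density scans may count them (they are real evidence of mapping trouble in
a window), while the frameshift cascade excludes them via
`is_homozygous_alt()`.

# Coordinates

All internal coordinates are 1-based closed, the convention shared by VCF,
GFF3, IRanges and Biostrings; windowed outputs (window tables, BED) use
0-based half-open bounds as BED requires. Keeping the I/O convention
internally means no shifts at any parser boundary; the only conversions are
in the window/BED writers, which are trivially auditable.

# Indel normalization

VCF permits many sequence-equivalent representations of one indel; an
insertion inside a homopolymer can be reported at any base of the run.
`normalize_variants()` trims the shared suffix then prefix and shifts the
edit left while it remains sequence-equivalent, yielding the parsimonious
left-aligned representation. Two properties are enforced by tests: applying
the raw and normalized record to the chromosome produces identical
sequences, and normalization is idempotent. Degenerate cases at position 1
(no anchor base remains to the left) keep the last valid representation
rather than inventing a right-anchored one.

Normalization matters scientifically because effect-prediction software
that annotates the raw representation can call a "frameshift" whose
left-aligned edit lies outside the coding sequence entirely — the pseudo
frameshifts the audit below is designed to expose.

# Density scans and window statistics

Windows are fixed and anchored at coordinate 0 — not sliding — so that
counts are exactly conserved (the sum over windows equals the input count)
and a 1-Mb window is exactly the sum of its two 0.5-Mb halves. A variant is
assigned by its normalized start position only, even when a deletion spans
a boundary; double counting would break conservation. Gene membership for
the gene-rich annotation uses the gene *start* for the same reason. A
window is gene-rich when *strictly more than* 50 genes start within 0.5 Mb.
Windows whose N fraction exceeds 0.5 are gap-flagged, so zero-count windows
over assembly gaps are reported as unassessable rather than "conserved".

Per-chromosome linear densities are reported relative to the densest
chromosome (value 1.0, ties broken by chromosome order), which makes the
two lines comparable on one axis despite a tenfold rate difference.

# Introgression segment calling and classification

`call_dense_segments()` seeds on windows at or above a density threshold
(SNPs/Mb, scaled to the window width), merges runs separated by at most
`merge_gap` (default 1) non-qualifying windows, and never seeds on or
bridges across gap-flagged windows. The classifier then works on the union
of both lines' segment footprints, comparing each line's mean density
against its own genome-wide background median:

| line A (low divergence)   | line B (high divergence)      | class                 |
|---------------------------|-------------------------------|-----------------------|
| ≥ 5,000 SNPs/Mb           | ≤ 0.1 × its median            | `reference_from_wild` |
| ≥ 5,000 SNPs/Mb           | ≥ 2 × its median              | `reference_divergent` |
| ≥ 5,000 SNPs/Mb           | near its median               | `lineA_specific`      |
| background                | ≥ 2 × its median              | `lineB_divergent`     |

The absolute 5,000 SNPs/Mb anchor for the low-divergence line and the
relative 2× / 0.1× factors for the high-divergence line reflect that "high"
is absolute for a line whose background is ~900 changes per Mb but can only
be relative for a line living at ~9,000 per Mb. Both-high segments carry a
note recording the alternative reading (an introgression in one line later
transferred to the other), which window counts alone cannot distinguish;
allele-identity sharing is deliberately not used for classification. A
third line's window profile can be attached as supporting evidence
(`third_line_concordance()`: elevated over at least half the segment's
windows), but never changes the class.

# The frameshift audit cascade

`run_cascade()` applies, in order: candidate selection → homozygosity →
detectable expression → pseudo-frameshift screen → impact classification.

**Candidates** (`fs_candidates()`) are the union of two routes: indels whose
normalized footprint intersects a CDS interval with a length change that is
not a multiple of 3, and indels carrying an upstream "frameshift"
annotation tag. The union matters: annotation artifacts must *enter* the
audit to be exposed.

**Expression** (`expression_filter()`) keeps genes whose maximum coverage
over their exons is at least 200 — the literal reading of "relative maximum
below 200 is nondetectable", so a maximum of exactly 200 is kept and 199 is
dropped. Genes absent from the track count as silent, with a warning.

**Pseudo-frameshift detection** (`detect_pseudo_fs()`) is decided by an
edit-and-translate comparison, not by pattern-matching indel contexts. The
edit is applied to the chromosome, every CDS interval is projected through
the edit (boundaries inside a deleted span snap to the nearest surviving
base; an insertion point sitting exactly on an interval end stays outside
the feature), the spliced CDS is re-extracted strand-aware and translated
to the first stop. The reason labels are explanatory tags over this single
underlying fact:

* `outside_cds_after_normalization` — the left-aligned edit no longer
  touches any CDS interval (the classic homopolymer-at-the-splice-border
  artifact);
* `inframe_after_normalization` — the net in-CDS length change is a nonzero
  multiple of 3 (a change of zero is not "in-frame", it simply leaves the
  CDS alone and falls through to translation);
* `border_artifact` — the changed bases touch a splice junction or the
  start/stop codon and the protein is unchanged;
* `protein_unchanged` — the protein is unchanged for any other reason, e.g.
  an insertion anchored on the stop codon's last base that lands entirely
  after the CDS.

Edits that destroy a splice donor/acceptor dinucleotide are reported with a
`splice_disrupted` flag but still audited on the naive projected CDS; no
isoform re-splicing is modelled. Incomplete gene models withhold the
verdict rather than guessing.

**Impact classes** (`classify_protein_impact()`): with reference length
`L`, mutant length `M` and first difference at `d`, a mutant shorter than
half the reference is `truncated_major` (the operational reading of
"missing most of the protein": 0.5 cleanly separates it from the terminal
categories); differences confined to the final or initial quarter of the
protein are `altered_C_terminal` / `altered_N_terminal` (the "~25% of the
protein ends" convention, tunable via `terminus_fraction`); a longer mutant
diverging only in the final quarter is `extended_C_terminal`; anything else
falls back to `truncated_major`.

Genes carrying more than one candidate are audited per variant and flagged
(`multi_candidate_gene`); compound-edit haplotypes are not modelled. The
cross-accession matrix (`accession_matrix()`) matches on normalized
(chrom, pos, ref, alt) identity — carrying *some* indel in the same gene
does not count.

# Marker design

`select_marker_indels()` keeps homozygous indels of 10–350 bp;
`design_amplicon()` centers a ~150 bp amplicon on the indel (minimum 30 bp
flanks), flags flanks that are >80% one nucleotide or contain N, and
reports both allele product sizes; `gel_resolvable()` requires a ≥10 bp
difference with both products ≤500 bp, matching what a 3% agarose gel
separates. The 10 bp floor mirrors the smallest practical size marker in
the fine-mapping setting this emulates. No melting-temperature or dimer
modelling is attempted — the flank sequences are exported verbatim for an
external primer tool.

# The synthetic study and what it does (not) show

The generator builds a 3 × 5 Mb genome (uniform base composition, planted
N-runs), gene-rich arms at 120 genes per 0.5 Mb versus 5 in the
pericentromere (so the >50 threshold separates them), and two call sets at
the study's background rates: one change per 1,100 bp (line A) and per 111
bp (line B), with indels 15% of changes on the arms versus 5% in the
pericentromere (the threefold euchromatic enrichment the density scan
should recover) and 2% of background calls emitted heterozygous. Four
segments, one per pattern class, are planted at window-aligned bounds
(e.g. 30,000 SNPs/Mb for the line-B-specific peak; 50/Mb for the wild-
introgression "absence" signature). Indel lengths are geometric, capped at
326 bp — the cap chosen as the largest insertion such a comparison has been
observed to produce, not as a target.

Frameshift candidates are planted *by construction*: genuine ones as 1–2 bp
mid-CDS edits (early for truncations, late for C-terminal effects, a
stop-free insertion near the terminus to seek an extension, plus
minus-strand cases), pseudo ones as a homopolymer insertion that
left-aligns across the splice acceptor into the intron, an insertion at a
donor junction duplicating the intron's first base, an in-frame deletion of
the stop codon, and an insertion anchored on the stop codon's last base.
Planted pseudo candidates are all protein-preserving, so the manifest
verdict and the brute-force translate-and-compare oracle agree by design.
Two cases are deliberately absent: mid-CDS in-frame indels are never
tagged as frameshift candidates (a realistic annotator calls them in-frame
indels), and no genuine frameshift is planted with an N-terminal-confined
impact, because a single frameshift alters everything downstream — that
class is exercised on constructed protein strings instead. Background
indels are kept out of coding sequence (±400 bp) so the audit ground truth
is exactly the planted candidate set; a dedicated arm region is likewise
reserved for the 30 planted marker-grade indels.

Everything derives from one master seed through fixed per-stage offsets;
regeneration is byte-identical. What passing these tests does *not* show:
the generator has no read-level error model, no mapping bias, no
base-quality structure, uniform GC, regularly spaced single-isoform genes,
and annotation tags emulated by construction rather than by running an
external predictor. Recovery of planted truth validates the *logic* of the
pipeline, not its robustness to real sequencing artifacts.

# Numerical and scale choices

The toy scale (3 × 5 Mb, ≥10 windows per chromosome) keeps the full
simulate-and-audit cycle to seconds-to-tens-of-seconds per seed; the test
suite runs the cascade loop closure across 10 seeds on single-chromosome
replicates and segment recovery across 20 seeds, and the acceptance script
repeats the same measurements from scratch under its own seed. Rate
recovery is asserted within 3 Poisson standard deviations per chromosome —
the natural sampling bound given that planted counts are Poisson draws.
Thresholds that are scientific constants (100× depth, QD 2, FS 60, MQ 40,
−8, −12.5, 200 expression, >50 genes, 10 bp gel floor, 25% termini, 50%
truncation) are defaults, each overridable per call.

# Known limitations

* Coordinate-projection translation cannot rescue a frameshift whose
  normalized representation deletes across a splice junction; such calls
  are audited naively and flagged, not re-spliced.
* Segment classification is density-only; shared-identity evidence between
  lines is reported (Jaccard-style position overlap can be computed from
  the call sets) but never drives the class.
* The homology-based curation that can rescue apparently broken genes
  (mis-annotated reference models, partial gene models) is out of scope; a
  free-text curation column is the designated place for such evidence.
* Sub-window segment bounds are not estimated; bounds are window-aligned,
  so the honest resolution is one window.
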