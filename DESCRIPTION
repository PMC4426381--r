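Package: varaudit
Title: Parental-Line Variant Filtering, Density Scans, Frameshift Auditing
    and InDel Marker Design
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-variant-calling analysis toolkit for pairs of inbred
    parental lines resequenced against a common reference genome, modelled
    on tomato mapping populations. Provides GATK-style hard filtering of
    VCF calls, indel left-alignment normalization, fixed-grid windowed
    SNP/InDel density scans with gene-rich and assembly-gap annotation,
    classification of high-density windows into putative introgression
    pattern classes, a frameshift-InDel audit cascade that detects
    pseudo frameshifts mis-called by effect-prediction software via
    edit-and-translate comparison, protein-impact classification,
    cross-accession frameshift sharing matrices, and InDel-based PCR
    size-marker design. Ships a deterministic synthetic genome/VCF fixture
    generator with a machine-readable truth manifest so every stage can be
    validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
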