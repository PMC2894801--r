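Package: probemapr
Title: Genome-Based Mapping and Transcript Annotation of Expression Array Probesets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps short oligonucleotide expression-array probes to a genome
    and to spliced transcript sequences allowing at most one mismatch,
    discards promiscuous probes that hit more than a configurable number of
    genomic locations, and annotates manufacturer probesets to transcripts
    under the rule that at least half of a probeset's probes must match the
    transcript footprint, where footprints include a doubled annotated
    3' UTR or a species-level 3' extension for transcripts lacking one.
    Unannotated probesets are profiled by where their probes fall relative
    to gene models (exon, UTR, intron, intergenic, region borders) and
    summarised as ternary coordinates.  Downstream audits classify
    probesets annotated to multiple genes (paralogy, genomic overlap, or
    unexplained), group probe placements by mismatch status and SNP
    overlap, and compare annotation tables from different providers.  A
    fixture simulator generates synthetic genomes, gene models, array
    designs, variants and paralog tables with a planted ground truth so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stringr,
    tibble,
    tidyr,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
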