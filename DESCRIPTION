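Package: repscreen
Title: Targeted Long-Read Screening of Repeat Expansion Disease Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagnostic screening of tandem-repeat expansion diseases from
    targeted long-read sequencing data. Measures per-read repeat copy-number
    change at catalogued disease loci from aligned reads, estimates two-allele
    genotypes, ranks loci against a control cohort, decomposes expanded repeat
    tracts into motif units (waterfall matrices), applies a rule-based
    pathogenicity triage, classifies allele-level CpG methylation, and reports
    adaptive-sampling enrichment QC. Ships a synthetic-data generator (mini
    genomes, long reads with ground-truth alignments, control cohorts,
    methylation tables) so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
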