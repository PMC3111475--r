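Package: ldrscan
Title: Low-Diversity-Region Scans and Introgression Genealogy Analysis for
    Pooled Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting selective-sweep footprints in domesticated
    genomes from pooled two-platform sequencing data. Implements error-filtered
    Watterson theta estimation from per-site allele read counts, sliding-window
    diversity scans with a genome-shuffle-calibrated low-diversity-region (LDR)
    cutoff, genealogy analysis of LDRs shared between two domesticated taxa
    (genetic distance, haploid Weir-Cockerham Fst, a conditional
    Kolmogorov-Smirnov D statistic against coalescent-simulation nulls under
    independent versus sequential domestication histories), and an Fst-triplet
    screen for candidate domestication genes carrying nonsynonymous divergent
    sites. A two-phase coalescent simulator (selfing-suppressed recombination
    after domestication, freely recombining wild phase) with pooled-read
    emulation makes every stage of the pipeline testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    data.table,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
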