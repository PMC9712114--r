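Package: hapcells
Title: Haplotype-Specific Copy Number and Structural Variation Analysis
    for Single-Cell Whole Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Infers haplotype-specific copy number states in single-cell
    whole-genome sequencing data with a hidden Markov model using
    Beta-Binomial emissions on phased haplotype-block allele counts, and
    quantifies foreground patterns of cell-to-cell structural variation:
    high-level amplification amplitude variance, parallel allelic copy
    number alterations, serriform (serrate) breakpoint variability,
    chromosome missegregation, whole-genome-doubling-aware copy number
    transformation distances, parsimony event rates on single-cell
    phylogenies, and allelic imbalance in matched single-cell RNA data.
    Includes a seeded simulator of clone-structured cell populations with
    known haplotype-specific ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    ape,
    cluster,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
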