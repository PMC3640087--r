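Package: famfates
Title: Gene-Family Expansion, Duplication Epochs, QTL Co-Localization and
    Paralog Expression Fates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide gene-family studies in paleopolyploid
    plant genomes: parsing gene annotations and collinearity blocks,
    classifying duplicate genes as segmental (WGD), tandem, proximal or
    dispersed, dating duplication blocks to whole-genome
    duplication/triplication epochs from synonymous substitution rates
    (NG86 with Jukes-Cantor correction), associating genes with QTL marker
    loci by genomic window, normalizing RNA-seq counts to RPKM and
    reference-gene-relative expression, clustering expression profiles, and
    classifying paralog-pair expression divergence and gene fates
    (non-/sub-functionalization). Includes a truth-labelled synthetic
    genome and expression generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    ape
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr,
    optparse
Config/testthat/edition: 3
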