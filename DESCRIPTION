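Package: hybridscan
Title: Genomic Instability Analysis for Interspecific Hybrid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for short-read surveys of interspecific hybrid
    genomes, built around budding-yeast hybrids. Estimates per-species genomic
    contributions with a diagnostic k-mer surrogate for competitive read
    mapping, calls whole-chromosome aneuploidy from windowed read depth with
    repeat-window masking and a relative +/-30 percent rule, classifies
    mitochondrial inheritance and its concordance with the nuclear majority,
    computes alignment-free shared-k-mer distance matrices with PHYLIP/NEXUS
    export, and maps loss-of-heterozygosity segments from parental
    single-nucleotide markers. Includes a synthetic hybrid-cohort generator
    (parent genomes, read sets, truth tables) so every stage is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    yaml
Config/testthat/edition: 3
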