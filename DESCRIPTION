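Package: gripr
Title: Gamma-Retrovirus Integration Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis toolkit for gamma-retrovirus integration profiling
    (GRIP). From a set of mapped proviral insertion sites, identifies and
    ranks significantly targeted genes by a windowed hypergeometric test
    against the union-of-gene-windows mappable genome, tests for
    post-integration clonal selection (proviral orientation bias and
    junction-fragment copy numbers), profiles insertions against
    transcription start sites and chromatin-mark peak sets, quantifies
    enrichment of annotated gene sets (e.g. cancer drivers) among top
    targets, and assesses overlap of top gene lists by Monte-Carlo
    simulation.  Includes a seeded synthetic-data generator producing toy
    genomes, peak sets and biased insertion datasets so that every pipeline
    stage is testable at desk scale, plus a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    S4Vectors,
    GenomicRanges,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
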