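Package: trgstrat
Title: Taxonomically Restricted Gene Detection and Caste-Biased
    Expression Enrichment
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomics pipeline for identifying taxonomically
    restricted genes (TRGs) in a focal genome. Implements a two-tier
    homology search (protein set first, then translated genome) built on
    an exact Smith-Waterman local aligner with Karlin-Altschul E-value
    statistics, a seven-way phylostratigraphic classification of genes
    (orphan through metazoan-conserved), per-class gene characteristics,
    inference of duplication origin for restricted genes, and
    contingency-table tests for enrichment of TRGs among caste-biased
    expression sets. Ships a seeded synthetic comparative-genomics
    generator with full ground truth so every stage can be validated
    end to end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
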