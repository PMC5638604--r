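Package: paradapt
Title: Two-Timescale Parallel Adaptation Analysis from Pooled Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for detecting parallel adaptation between
    latitudinally separated populations and between diverged clades of
    Drosophila. Implements pooled-sequencing population genetics (nucleotide
    diversity, per-SNP and windowed F_ST, mid-p exact outlier tests with
    per-chromosome-arm false discovery rates), codon-aware SNP effect
    annotation, McDonald-Kreitman tests with alpha and the direction of
    selection index, hypergeometric and SNP-count-matched bootstrap tests of
    cross-species outlier sharing, expression-parallelism statistics, and
    synthetic data generators with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
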