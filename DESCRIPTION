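Package: msatlas
Title: Post-Assembly Analytics for a Two-Genotype Alfalfa Expression Atlas
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analytics for a de novo RNA-seq transcriptome atlas of the two
    alfalfa (Medicago sativa) subspecies sampled over six tissues with three
    biological replicates: RPKM normalization and read-retention filtering,
    expression-breadth classification (expressed, tissue-specific,
    genotype-specific), a deterministic nonparametric M-D differential
    expression caller, replicate-concordant SNP filtering and classification,
    single-linkage gene-family clustering with a ploidy-aware chi-square
    expansion test, six-frame scanning for nodule-specific cysteine-rich
    (NCR) peptide motifs, Fisher GO over-representation, windowed feature
    densities, a seeded synthetic-data generator with planted truth, and a
    pipeline driver emitting machine-readable summary tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
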