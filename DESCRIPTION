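Package: coseg
Title: Co-Segregation Multi-Omics Analysis for Aphid Effector Candidates
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a bulk-segregant co-segregation workflow for nominating
    insect virulence and avirulence effector candidates from paired
    transcriptomic and proteomic evidence. Provides a synthetic F1-cross
    multi-omics generator (Mendelian dominant virulence locus, negative
    binomial counts, log-normal label-free intensities with
    abundance-dependent dropout), virulence-index phenotyping and bulk
    selection, a count-based differential expression engine (trimmed mean of
    M-values normalisation, method-of-moments dispersion with shrinkage,
    negative binomial conditional exact test, Benjamini-Hochberg control),
    Perseus-style label-free proteomics (downshift imputation, Welch SSDA
    testing, signed relative fold changes, exclusive-detection calls), and
    multi-dataset evidence integration with candidate filtering and category
    enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite,
    optparse
biocViews: Transcriptomics, Proteomics, DifferentialExpression,
    GeneExpression, Normalization
Config/testthat/edition: 3
RoxygenNote: 7.3.3
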