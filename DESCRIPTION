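Package: boescan
Title: Suppressor Calling and Statistics for Bypass-of-Essentiality Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing systematic bypass-of-essentiality (BOE)
    suppressor screens in fission yeast. Implements candidate calling for
    three screen types: transposon insertion profiling (per-region G-tests of
    observed insertions against TTAA target-site counts), overexpression
    library sequencing (consistency-weighted BOE-scores from N-/C-end read
    counts across replicate screens), and bulk segregant analysis of point
    mutants (variant-effect classification and multi-rule SNP filtering).
    Provides downstream statistics relating bypassability to gene features,
    protein complexes and network-level functional relatedness (Fisher and
    rank tests, permutation tests, ROC analysis, average-linkage clustering,
    pair-enrichment against enumerated backgrounds), together with a
    synthetic-data generator that emulates the statistical structure of each
    screen for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
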