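Package: rpoaprofiler
Title: Species-Level Profiling of Faecalibacterium from rpoA Amplicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Degenerate primer design, in-silico PCR and specificity
    screening, curated rpoA reference-library handling, tiered
    identity-threshold classification of amplicon sequence variants,
    per-sample composition and prevalence summaries, cohort exclusion
    cascades, and the accompanying statistical layer (rank tests,
    Bray-Curtis ordination, PAM clustering, vector fitting, PERMANOVA and
    multivariable linear diet associations with FDR control) for
    species-level profiling of the gut genus Faecalibacterium using the
    single-copy rpoA marker gene. Includes mock-community simulators so
    the whole pipeline can be exercised and validated without external
    sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    cluster,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
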