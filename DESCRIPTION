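Package: panelrp
Title: Variant Prioritization, Coverage-Ratio CNV Calling and Case
    Resolution for Targeted Retinal Dystrophy Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", role = c("aut", "cre"),
           email = "author@example.org")
Description: Implements the variant-interpretation computation behind a
    targeted gene-panel diagnostic workflow for autosomal recessive
    retinitis pigmentosa: a six-criterion variant prioritization cascade
    with a multi-predictor in-silico consensus, a cross-sample
    coverage-ratio caller for exon-level copy-number variants, per-gene
    coverage quality control, and per-family case resolution with
    inheritance-aware reclassification. A seed-reproducible synthetic
    cohort generator emits annotated variant tables, coverage matrices
    and pedigrees with known truth so the whole pipeline can be
    exercised and benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
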