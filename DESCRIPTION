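Package: rhythmochip
Title: Around-the-Clock ChIP-Seq Peak Calling, Cosinor Rhythmicity and
    Motif Enrichment
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for circadian (around-the-clock) ChIP-seq
    time courses: weighted tag loading with redundant-tag removal and
    fragment-size strand shifting; block-based peak calling against a
    matched input with quantile normalization, half-offset tiling merge
    and iterative peak border refinement; cosinor (harmonic regression)
    fitting of binding and expression time series with amplitude
    p-values, phase confidence intervals and a genotype/batch extension;
    temporal-profile clustering and circular phase statistics; motif
    scanning with empirical enrichment p-values against random region
    groups matched on size, TSS distance and gene expression; and a
    ground-truthed synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    limma,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    tools,
    optparse
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
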