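Package: dynamIR
Title: Intron Retention Dynamics and Their Chromatin Correlates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies intron retention (IR) from coverage and splice-junction
    data, calls retained/non-retained/dynamic introns, tests differential
    retention between cell types with the Audic-Claverie count statistic, calls
    nucleosome-free regions and positioned nucleosomes from NOMe-seq GCH
    methylation with Fisher exact tests against local background, assembles
    region-anchored sequence/methylation/histone feature tables, trains
    elastic-net and conditional-inference-forest classifiers with scaled
    variable importances, clusters splice-site-proximal GCH accessibility
    profiles, and adjusts H3K36me3 signal for nucleosome occupancy with a
    count GLM. A synthetic multi-omics generator plants IR-chromatin structure
    across five cell types so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    pROC,
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
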