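Package: saltomics
Title: Staged Differential Analysis for Salt-Stress Multi-Omics in
    Streptomyces
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reusable implementations of three bespoke computational
    procedures used to study the salt-stress response of Streptomyces
    coelicolor: a staged statistical workflow that calls untargeted LC-MS
    features differentially produced between salinity conditions over time
    (blank and retention-time filtering, a signal floor, pseudocounts, a
    fold-change prefilter, one-way and two-way ANOVA with
    Benjamini-Hochberg control and a 100-fold interaction gate); a
    Cappable-seq transcription-start-site caller (strand-aware 5' end
    counting, 5 nt single-linkage clustering, all-replicate consensus,
    cross-condition merging, and upstream/internal/antisense
    classification against gene models); and differential-expression
    rules over log2 fold-change tables (zeroing of non-significant fold
    changes, a 5-fold span criterion across conditions, a max-of-max
    salt-responsiveness rule, Fisher's exact gene-set enrichment, and
    conservation binning). A seeded synthetic-data generator emulates
    every input with known ground truth so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    methods,
    yaml,
    jsonlite,
    withr,
    optparse,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
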