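Package: vplotdiff
Title: Differential Chromatin Accessibility from ATAC-Seq Fragment V-Plots
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fragment-level ATAC-seq processing and nucleosome-aware
    differential accessibility analysis. Provides Tn5 insertion-offset
    correction, per-base coverage tracks, a coverage-threshold peak caller
    with summit-centered fixed-width intervals, degenerate-consensus motif
    scanning, motif-centric V-plot (fragment midpoint by fragment size)
    matrices, a sample-conditioned variational autoencoder with a
    chi-squared latent-space test for differential V-plots, motif deviation
    scores with background normalization, four-way open/closed region
    grouping with annotation enrichment, and a seeded nucleosome-aware
    fragment simulator with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
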