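Package: ridgemotif
Title: Motif-Based Ridge Attribution of Differential Chromatin Accessibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds summit-aware consensus ATAC-seq peak atlases from
    per-population peak calls, scans peak sequences against grouped
    transcription-factor position weight matrices using exact
    score-distribution thresholds, and fits ridge regression models of
    per-peak differential accessibility on the binary peak-by-motif matrix,
    with Cule-style coefficient significance and leave-one-motif-out
    delta-correlation attribution at peak subsets. Also provides the
    companion integration statistics: bulk gene k-means clustering,
    single-cell module scoring against bulk clusters, hypergeometric
    enrichment, gene-set distribution-shift tests, T-cell-receptor clonotype
    Jaccard overlap matrices and the Mantel permutation test, plus a fully
    deterministic synthetic-data generator with planted ground truth so the
    entire pipeline is exercisable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
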