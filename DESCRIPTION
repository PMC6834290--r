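Package: paralethal
Title: Paralog Buffering and Variable Gene Essentiality in CRISPR Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for genome-wide CRISPR-Cas9 fitness screens
    across panels of cell lines, focused on the contribution of paralog
    buffering to variable gene essentiality. Identifies multi-targeting
    sgRNAs by exhaustive PAM-aware alignment, aggregates guide-level
    log-fold changes into gene fitness scores, binarizes scores with a
    Gaussian mixture model boundary threshold, classifies genes as never,
    sometimes or broadly essential, annotates paralog pairs with sequence
    identity, duplication mode (whole-genome vs small-scale) and protein
    complex membership, calls putative synthetic lethal paralog pairs from
    expression-stratified differential tests with FDR control, and runs
    copy-number, nonsense-mutation and enrichment follow-ups. Includes a
    synthetic cohort generator (toy genome, guide library, screen and
    omics tables with planted ground truth) so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    nnet,
    jsonlite,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
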