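Package: chromomine
Title: Mining and Horizontal-Transfer Analysis of Chromodomain-Containing
    Gypsy LTR Retrotransposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for discovering chromodomain-containing
    Gypsy (Metaviridae) LTR retrotransposons in genomic sequence,
    annotating their structure (LTR pairs, target-site duplications, ORFs,
    enzymatic domain architecture, CCHC motif, polypurine tract and
    primer-binding site), clustering elements into families, building
    neighbor-joining phylogenies with bootstrap support, and evaluating
    candidate horizontal-transfer events through Poisson-corrected
    amino-acid distances and calibrated substitution rates.  Includes a
    synthetic-genome simulator that plants structurally realistic
    retroelements with full ground truth, an in-silico degenerate-primer
    PCR, and an end-to-end reproducible run orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
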