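Package: seedscreen
Title: Seed-Sequence Off-Target Analysis for Arrayed siRNA Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of seed-sequence driven off-target effects in arrayed
    siRNA screens. Turns raw plate fluorescence into robust per-siRNA scores
    (plate-median normalised log survival, median/MAD z, minimum over
    replicates), extracts hexamer and heptamer seeds from guide strands,
    tests the significance of repeated seeds among top-scoring siRNAs by
    sampling, detects seeds enriched in high-scoring siRNAs with a
    pre-ranked set-enrichment engine (enrichment score, NES, permutation
    FWER), removes siRNAs carrying enriched seeds and re-tests known-gene
    enrichment, matches enriched seeds against mature miRNA sequences, and
    classifies confirmation-assay evidence into hit, off-target,
    unconfirmed and false-positive calls. Includes a synthetic screen
    generator with planted gene and seed effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
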