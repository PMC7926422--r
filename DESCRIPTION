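Package: ppredit
Title: PPR-Code Target Prediction and Differential C-to-U RNA Editing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing plant organellar C-to-U RNA editing and the
    pentatricopeptide repeat (PPR) proteins that specify editing sites. Builds
    log-ratio scoring tables for the PPR-RNA recognition code from alignments
    of known editing factors to their targets, aligns PLS-class PPR proteins
    to candidate editing sites (anchoring the E2 motif two nucleotides
    upstream of the edited cytidine) and ranks candidate factors; quantifies
    per-site editing extent from per-position nucleotide counts and calls
    differential editing between genotypes with an exact Fisher test,
    Simes-Hochberg multiple-testing correction and pseudocounted odds ratios;
    compares binding-site scores of putative orthologues between species where
    a site is editable and species where it is not; and simulates every input
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    Rsamtools,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
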