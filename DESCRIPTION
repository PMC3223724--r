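Package: locweaver
Title: Genome-Wide Protein Subcellular Localization Prediction for
    Gram-Negative Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based prediction of protein subcellular localization in
    gram-negative (diderm) bacteria. Provides scanners for N- and C-terminal
    sorting signals (Sec and Tat signal peptides, lipoboxes, twin-glycine
    bacteriocin leaders, the beta-barrel C-terminal signature, transmembrane
    hydropathy spans), packaged domain registries for export machinery,
    secretins/ushers and signal peptidases, genome-context detection of
    secretion-system loci and their substrate candidates, a decision tree that
    integrates scanner output with external predictor tables and
    location-informative domains under majority voting, cross-genome
    ortholog-group consistency checking, validation of N-termini from observed
    semi-tryptic peptides, and a deterministic synthetic-data generator with
    planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
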