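Package: immunorank
Title: Percentile Rank Scoring and Electronic Sorting of Expression Compendia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for cross-array comparison of gene expression by
    per-array percentile rank scores.  Each array's probe sets are ranked
    ascending by signal and sliced into approximately equal groups (default
    100), yielding integer rank scores comparable across heterogeneous
    experiments.  On top of the rank scores the package builds rank-based
    expression (RBE) distribution curves per probe set and cell group,
    gene plasticity scores (GPL, the interquartile range of rank scores),
    average rank scores (ARS), and signed Wilcoxon marker evaluation
    scores (MES) against an all-groups background.  It also supports
    electronic sorting (retrieval of samples and series whose rank score
    for a gene lies in a chosen range), calibration of a rank-score
    threshold for undetectable expression from Affymetrix-style detection
    calls, marker-panel sample quality control, and a synthetic compendium
    generator with planted markers, plastic genes and quality-control
    violations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
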