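Package: nodeconnect
Title: Nodes-and-Connections RNAi Screening and Interaction-Map Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for iterative "nodes-and-connections" RNAi knockdown
    screening campaigns: clone-level viability hit calling with a two-clone
    ANOVA criterion, seed-and-expand assembly of generation-annotated gene
    interaction maps with predicted-only nodes, Prognosis Marker Expression
    (PME) immunohistochemistry scoring with a marginal-resampling permutation
    null and tail chi-square synchronization test, a median-split
    Kaplan-Meier prognostic screen with Benjamini-Hochberg false discovery
    rate control, treatment-response classification of normalized expression,
    and synthetic-data generators emulating every input so the whole pipeline
    is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
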