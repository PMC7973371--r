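Package: myonet
Title: Temporal Network Analysis and Combinatorial Attack for
    Inflammatory Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for time-course case-control RNA-seq of
    inflammatory disease models. Filters and tests gene-level counts for
    per-timepoint differential expression with a negative-binomial Wald
    test, classifies genes into temporal onset/persistence groups, runs
    one-sided Fisher's exact pathway enrichment, scores genes by
    Fisher-combined significance across timepoints, extracts a
    maximum-weight connected subnetwork from merged pathway interaction
    networks via a prize-collecting Steiner tree heuristic, quantifies
    node criticality by "attackness" (giant-component percolation under
    targeted node removal, single and combinatorial), and prioritizes
    drug-repurposing targets from a ChEMBL-style drug-target table.
    Includes a synthetic-data generator emulating the full study design
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
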