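Package: comodhom
Title: Direction Homogeneity of Gene Co-Expression Modules in Case-Control Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds weighted gene co-expression networks separately for case and
    control samples of two-condition expression studies, detects modules by
    topological overlap clustering, and classifies each module as up-regulated,
    down-regulated or mixed from the differential-expression directions of its
    members. Includes cross-dataset common-module identification, probe
    reannotation rules for recovering long non-coding RNAs from coding-gene
    microarrays, guilt-by-association functional annotation of lncRNAs via
    their most correlated mRNAs, hypergeometric gene-set enrichment, and a
    synthetic-data generator that plants direction-coherent correlated modules
    so the whole workflow is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
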