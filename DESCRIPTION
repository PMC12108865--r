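Package: fpcam
Title: Weighted Dictionary-Driven Cell-Type Annotation for Clustered
    Single-Cell RNA-Seq Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates transcriptomic cell clusters with cell-type labels
    by scoring them against a curated marker-gene voting dictionary.
    Marker genes carry per-cell-type weights derived from literature vote
    counts; cluster-level marker statistics (Seurat FindAllMarkers
    convention) are converted to per-gene expression proportions and
    matched against the dictionary to produce a cluster-by-cell-type
    similarity matrix. Labels are assigned through a threshold rule on
    the gap between the top score and the row median, optionally adding a
    secondary label. Also provides a multi-annotator evaluation harness
    (Boyer-Moore majority-vote pseudo-reference, per-annotator accuracy,
    range statistics), a synthetic-data generator with planted ground
    truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
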