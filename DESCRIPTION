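Package: dkbuild
Title: Building a Disease-Centric Knowledge Base from Vertical Portal Dumps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for constructing a disease-centric medical knowledge base
    from the semi-structured dumps of health web portals. Per-portal records
    (navigation rows, lists, tables, infoboxes) are mapped onto
    vertically-partitioned two-column property tables and materialised as
    typed RDF-style data graphs against a fixed diabetes domain schema.
    Portal graphs are fused by cleansing conflicting class assignments with a
    reference disease code list plus majority voting, matching equivalent
    instances across portals, and merging matched clusters. A distance-based
    expectation-maximisation procedure built on eigenvector centrality then
    carves the diabetes-centric subgraph out of the unified graph. A
    synthetic-corpus generator with planted ground truth makes every stage
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
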