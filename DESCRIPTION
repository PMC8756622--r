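Package: kgap
Title: Knowledge-Graph Evidence-Path Aggregation for Drug Target Illumination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and queries a five-node-type chemogenomic knowledge graph
    (Drug, Signature, Gene, Cell, Concept) linking approved-drug indications to
    LINCS-style differential-expression signatures, enumerates
    Drug-Signature-Gene evidence paths above a z-score threshold, and
    aggregates them per gene with Stouffer's weighted-z function in
    degree-weighted (D) and z-weighted (Z) modes to produce a ranked candidate
    target list.  Includes ROC/AUC validation of rankings against known-target
    gene sets, TIN-X-style non-dominated (Pareto) prioritization over
    bibliometric novelty and importance, a Target Development Level annotator
    for surfacing understudied (Tdark) candidates, a synthetic knowledge-graph
    generator with planted drug-to-gene signal for end-to-end testing, and a
    packaged Parkinson's disease drug-set fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
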