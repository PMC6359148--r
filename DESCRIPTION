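Package: netreporter
Title: Network-Based Reporter Biomolecule Discovery and Drug
    Repositioning Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, testable implementation of a
    systems-biomedicine biomarker pipeline for case/control
    transcriptomes: gene-wise differential expression with an
    empirical-Bayes moderated t-statistic and Benjamini-Hochberg false
    discovery control, cross-dataset mutual DEG intersection, gene-set
    overrepresentation by Fisher's exact test, protein-protein
    interaction hub mining with a dual-metric (degree and betweenness)
    rule and MCODE-style dense-module detection, reporter transcription
    factor and microRNA prioritization by normalized z-score
    aggregation over a regulatory network, Cox prognostic-index risk
    stratification with Kaplan-Meier and log-rank evaluation, and
    hypergeometric drug-target repositioning.  A synthetic-data module
    generates every pipeline input with planted ground truth so all
    stages can be validated without external database access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
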