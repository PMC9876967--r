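Package: respmarker
Title: Discrete Bayes Marker Discovery for Antidepressant Treatment Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and validation pipeline for blood gene-expression
    markers of antidepressant response. Screens RNA-seq count matrices with
    TMM normalization and a gene-wise negative-binomial likelihood-ratio
    test, quantifies candidate genes from qPCR dilution-series standard
    curves with reference-gene (B2M) fold changes, classifies responders
    with a discrete Bayes decision rule over quantile-discretized markers,
    and selects marker combinations by leave-one-out frequency voting.
    Includes a seeded synthetic-data generator emulating the statistical
    structure of a two-group responder/non-responder cohort so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    edgeR,
    jsonlite
Suggests: testthat (>= 3.0.0), yaml, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
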