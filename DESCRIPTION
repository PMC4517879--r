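Package: ripkit
Title: Simulation and Scorer-Evaluation Tools for Infant Respiratory
    Inductive Plethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating manual-scoring workflows for
    infant respiratory inductive plethysmography (RIP) signals. Generates
    synthetic ribcage/abdomen records realizing the six canonical respiratory
    patterns (synchronous and asynchronous breathing, sigh, respiratory
    pause, movement artifact, unknown), splices labeled segments into
    continuous records with smooth cross-fade transitions, assembles
    training, evaluation and quality-control records, simulates human
    scorers with configurable confusion and boundary error, and computes the
    full scorer-evaluation statistics: sample-wise Fleiss' kappa with
    bootstrap uncertainty and interpretation bands, consensus labeling,
    conditional-probability confusion matrices with segment-length
    sensitivity, and scoring-rate metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
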