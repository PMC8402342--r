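Package: panelswap
Title: Diagnostic Biomarker Panel Optimization for Host-Response Gene Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing and evaluating multi-marker host-response
    diagnostic gene panels. Provides synthetic multi-cohort expression
    simulation with class-conditional fold changes and batch effects,
    abundance and dynamic-range marker quality control with tier ranking,
    two-phase greedy forward feature selection scored by cross-validated
    multi-class AUROC, multi-layer-perceptron ensemble and SVM classifiers
    emitting per-class probability scores, four-band likelihood-ratio
    clinical metrics for rule-in/rule-out interpretation, and hypergeometric
    gene-set over-representation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    glmnet,
    nnet,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
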