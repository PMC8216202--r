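Package: metasym
Title: Metacognitive Asymmetry Analysis with Response-Conditional Type-2 ROC Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pre-registered analysis pipeline for masked visual discrimination
    experiments with continuous confidence ratings. Simulates observers
    performing a staircased (1-up-2-down) discrimination task under an
    unequal-variance signal detection model, applies trial- and
    participant-level rejection criteria, extracts response-conditional
    type-2 ROC curves and their areas (metacognitive sensitivity), derives
    the asymmetry expected from an equal-variance signal detection observer
    matched in sensitivity, response bias and error-confidence distribution,
    and tests group-level hypotheses about presence/absence asymmetries in
    confidence, metacognitive sensitivity and response time with one-tailed
    t-tests and Jeffreys-Zellner-Siow (Cauchy-prior) Bayes factors.
    Includes the study's design analysis, exact noncentral-t power and
    Monte-Carlo Bayes-factor outcome proportions under a true null and
    under Cauchy-distributed true effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
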