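Package: stablerules
Title: Stable Explicit-Rule Classifiers for Patient Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Induces explicit if-then classification rules over categorical and
    ordered clinical risk factors with a bottom-up aggregative covering
    algorithm, and stabilizes them through an iterative procedure that measures
    per-rule stability under repeated stratified cross-validation, derives Core
    rules by premise intersection, diagnoses the instances responsible for rule
    instability (low-covering unstable rules, near-duplicate rules, ambiguous
    duplicated profiles) and removes them until every rule is fully stable.
    Includes rule covering/error/precision statistics, condition and variable
    relevance measures, symbolic conflict analysis with derived not-classified
    rules, Fisher exact rule significance, classifier performance metrics, a
    synthetic cohort generator with planted rules and instability sources, and
    a Manhattan-distance k-means dichotomizer for numeric expression
    signatures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
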