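Package: saltsynergy
Title: Additive Gene-Sodium Interaction Analysis for Nested Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing additive gene-environment interaction between
    the GNB3 C825T polymorphism (or any binary genetic factor) and dietary
    sodium intake on incident hypertension in cohort-based (nested)
    case-control studies. Provides contingency tabulation with crude odds
    ratios and Woolf confidence intervals, dummy-coded logistic regression by
    iteratively reweighted least squares, and the additive-interaction
    statistics RERI, attributable proportion and the Rothman synergy index
    with delta-method and bootstrap confidence intervals, together with a
    synthetic cohort generator (Hardy-Weinberg genotypes, two-class sodium
    exposure, configurable odds-scale effects and 1:k gender frequency
    matching) so the full analysis is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
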