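Package: bfrct
Title: Bayes Factors for Randomized Trial Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes Bayes factors for intervention effect estimates from
    randomized trials using only published summary statistics (effect size and
    standard error), contrasting a point null against half-normal, normal or
    uniform priors on the effect. Includes conversions from published trial
    summaries (odds/risk/rate ratios, confidence intervals, t statistics,
    2x2 counts, group standard deviations) to a common analysis scale,
    Jeffreys-style evidence classification, a packaged re-analysis of 75
    effect estimates from addiction trials with their published Bayes
    factors, and a synthetic two-arm trial simulator for studying operating
    characteristics and sequential Bayes-factor stopping rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
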