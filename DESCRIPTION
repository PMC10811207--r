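Package: diinest
Title: Dietary Inflammatory Index Scoring and Hierarchical Models for Nested Dietary Exposures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Dietary Inflammatory Index (DII) from food-frequency
    questionnaire data and relates it to mental-disorder scores (DASS-42) with a
    three-level hierarchical regression in which food effects are shrunk toward
    their nutrient-composition predictions and nutrient effects toward their
    inflammatory-weight predictions (empirical-Bayes / semi-Bayes estimation via
    restricted maximum likelihood). Includes FFQ-to-intake conversion with an
    energy-based exclusion rule, DASS-42 subscale scoring, a synthetic cohort
    generator for method evaluation, conventional simple and multiple linear
    model baselines, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
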