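Package: dietmoe
Title: Probabilistic Dietary Exposure and Margin of Exposure Assessment
    for Acrylamide in Baby Foods
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for probabilistic dietary exposure assessment of the
    process contaminant acrylamide in foods for infants. Reconstructs
    per-sample concentration datasets from published censor-aware summary
    statistics by constrained numerical adjustment, substitutes
    left-censored values below the limits of detection and quantification
    (middle-, lower- and upper-bound rules), builds the concentration
    distribution by bootstrap resampling with additive Gaussian
    measurement error, models daily consumption as a moment-matched
    log-normal, propagates both through a Monte Carlo exposure simulation
    per infant age group, and characterizes risk with Margin of Exposure
    (MOE) distributions against neurotoxic and carcinogenic BMDL10
    endpoints, including concern-threshold exceedance probabilities and
    empirical cumulative distribution functions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
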