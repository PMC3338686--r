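Package: trflpdyn
Title: Community Dynamics and Environmental Correlates from T-RFLP Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for terminal restriction fragment length
    polymorphism (T-RFLP) time series of microbial communities, motivated by
    ammonia-oxidizer monitoring in activated sludge. Turns fragment-analysis
    peak tables into aligned relative-abundance profiles (size window, T-RF
    binning, noise floor), quantifies temporal community change with a
    moving-window Pearson statistic, relates community structure to
    operational and environmental covariates by canonical correspondence
    analysis with Monte-Carlo permutation tests and forward selection, runs
    per-variable Mantel tests, predicts terminal fragment lengths of clone
    sequences by in-silico restriction digestion, and generates synthetic
    peak tables with planted environmental drivers for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
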