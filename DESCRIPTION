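Package: qstfst
Title: Qst-Fst Comparisons for Common-Garden Quantitative Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for contrasting quantitative-trait divergence (Qst) with
    neutral-marker differentiation (Fst) in structured plant populations raised
    in a common garden. Implements the multi-allelic Weir-Cockerham theta
    estimator with permutation significance, REML variance components for the
    population/family/block random-effects design with full-sib heritability and
    Spitze Qst, parametric-bootstrap confidence intervals, the
    Whitlock-Guillaume simulated neutral null for the Qst-Fst difference,
    Mantel and partial Mantel permutation tests with exhaustive enumeration at
    small population numbers, population-divergence models (likelihood-ratio
    tests, marginal means, altitudinal regressions), a GenePop reader, and a
    synthetic-data generator emulating a 13-population, two-subspecies
    full-sib common-garden study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    geosphere,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
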