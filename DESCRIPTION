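Package: lactgain
Title: Coupled Mechanistic and Breeding-Scheme Simulation of Selection
    Response on Dairy Lactation Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts selection response on lactation-efficiency traits in
    dairy cattle by coupling a reduced-form mechanistic bioenergetic model of
    the cow (daily energy acquisition and allocation over the lifetime, with
    reproduction and culling) to a stochastic breeding-scheme simulator
    (genomic truncation selection on a total merit index). Provides seasonal
    feed-environment generators for non-limiting and limiting nutritional
    scenarios, half-sib founder population sampling, sire-model variance
    component estimation, correlation-matrix bending, selection-index and
    Bulmer-effect arithmetic, deterministic genomic-accuracy formulas, a
    sparse multi-trait pedigree BLUP solver, and the three-step feedback loop
    that propagates correlated responses on acquisition/allocation traits
    back into the mechanistic model to re-simulate phenotypes under both
    environments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
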