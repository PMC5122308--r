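Package: sdcomplexity
Title: Sexual Display Complexity Scoring and Multimodel Inference for
    Behavioral Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the complexity of animal courtship
    displays from focal-sampling event logs and relating it to individual
    traits. Scores fixed-window posture sequences for richness (number of
    distinct postures), versatility (number of transitions between
    different postures) and their product, the sexual display complexity
    (SDC) score. Provides two-standard-deviation predictor
    standardization, all-subsets model generation with marginality and
    collinearity constraints, AICc-based model selection, Akaike weights,
    zero-method (full-average) model averaging with unconditional
    standard errors, prediction on the response scale, rank-based
    breeding-status comparisons, and randomization tests of assortative
    mating against a random-pairing null. A fully deterministic synthetic
    study generator (Markov-chain display sequences driven by a latent
    age- and date-dependent quality) supports end-to-end testing and
    power analysis without field data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
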