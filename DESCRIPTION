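Package: cprgame
Title: A Common-Pool Resource Game with Bioeconomic Yield Analysis and
    Learning Harvesters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a group of harvesters exploiting a renewable
    common-pool resource with logistic regrowth and Cobb-Douglas harvest
    production. Provides closed-form and numerical yield analysis
    (maximum sustainable yield, maximum economic yield, sustainable and
    profitable effort bounds, resource-level equilibria, and the fraction
    of the action space that is simultaneously sustainable and
    profitable), plus decentralised tabular Q-learning agents whose
    reward weighs an individual profit trend against a collective
    sustainability trend. Experiment harnesses sweep group size and the
    cost/reward-weight grid, returning tidy tibbles ready for dplyr and
    ggplot2.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
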