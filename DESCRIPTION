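Package: permcrt
Title: Permutation-Based Multiple Testing and Confidence Sets for
    Cluster Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inference for cluster randomized trials with multiple
    outcomes using permutation tests built on studentized quasi-score
    statistics. Provides family-wise error rate control via Bonferroni,
    Holm, and Romano-Wolf stepdown corrections computed from permutation
    distributions, and simultaneous confidence sets located by a
    Robbins-Monro stochastic approximation search. Includes generators
    for multi-outcome cluster-trial designs (correlated Gaussian pairs,
    mixed Poisson and Gaussian outcomes, and a three-outcome design with
    baseline period and temporally decaying cluster-period random
    effects) and a simulation harness estimating family-wise error
    rates, simultaneous coverage, and interval widths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
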