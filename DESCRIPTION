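Package: phenorep
Title: Repeatability, Plasticity and Heritability of Breeding Phenology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for partitioning variance in longitudinal breeding-phenology
    records with crossed-random-effect linear mixed models, calibrated to the
    long-term Marion Island southern elephant seal monitoring programme.
    Provides an individual-based simulator of heritable arrival-date phenology
    (individual intercepts and moult-date reaction-norm slopes, year effects,
    age- and experience-dependent means, mother-daughter transmission),
    within-subject centring and design bookkeeping, likelihood-ratio tests for
    random slopes, AIC model ranking, repeatability with parametric-bootstrap
    confidence intervals, parent-offspring heritability with a randomized-dyad
    permutation test, and age-trend summaries. All user-facing functions take
    and return tibbles.
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
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
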