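Package: wcstsim
Title: Simulation and Group-Level Fitting of Wisconsin Card Sorting Test
    Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A process model of Wisconsin Card Sorting Test (WCST) performance
    built from four interpretable cognitive parameters: error sensitivity of a
    reinforcement-learning motivational update (mu), working-memory decay toward
    baseline (phi), softmax selection temperature (tau), and a feedback-valenced
    inner-speech bias on rule priorities (lambda).  Provides a seeded task
    environment with Heaton-style scoring of completed categories, perseverative
    and non-perseverative errors, and failures to maintain set; group simulation;
    fitting of parameter configurations to group behavioural profiles by random
    search over the mean squared error; parameter-recovery experiments; and the
    Bonferroni-corrected group contrasts (t-tests, one-way ANOVA with post-hoc
    tests) used to compare fitted groups.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
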