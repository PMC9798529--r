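Package: aromat
Title: Adaptive Bayesian Odor Detection Threshold Testing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Engine for a rapid adaptive odor detection threshold test run on a
    17-label peel-and-burst odorant card. A signal-detection psychometric model
    (guess-rate-floored probit with a detection threshold and a decision
    criterion) is fit by grid-based Bayesian updating after every yes/no trial;
    the next label is chosen greedily to minimise the expected posterior
    uncertainty of the threshold, and the complete 8-trial decision tree is
    precompiled into a lookup table for real-time use. Includes ASTM E679
    extreme-value scoring, false-alarm and quality-control flags, a virtual
    observer and twin-cohort simulator, and the cohort-level analyses used to
    characterise such tests (two-way ANOVA with Tukey HSD, floor-proportion
    chi-squared test, Falconer broad-sense heritability with Fisher-z
    uncertainty, propensity-score matching, ANCOVA and two-sample
    Kolmogorov-Smirnov comparison, test-retest reliability).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
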