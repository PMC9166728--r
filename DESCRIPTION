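Package: scmdiag
Title: Self-Consistency Model Analysis of Repeated Expert Diagnoses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying within-expert inconsistency in two-session
    diagnostic reader studies. Implements the self-consistency model (SCM),
    in which an expert samples an odd number of cues and decides by cue
    majority: closed-form accuracy, confidence and test-retest inconsistency,
    the Condorcet amplification relation, and a Monte-Carlo simulator.
    Includes a synthetic reader-study generator (per-case cue validities from
    a kind/wicked mixture, discrete confidence scales, incomplete designs),
    per-case and per-expert summary statistics, the maximum-confidence
    slating rule with baseline comparisons, Bayesian hierarchical logistic
    and linear regressions with crossed random intercepts for experts and
    cases (JAGS, with a fast maximum-likelihood fallback), and a Bayesian
    one-sample t-test on standardized effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    rjags,
    coda,
    glmmTMB,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
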