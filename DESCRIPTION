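Package: normdev
Title: Gaussian-Process Normative Modelling of Cortical Development and
    Individual Deviation Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits per-vertex Gaussian-process normative models of cortical
    thickness development (age and sex covariates, empirical-Bayes
    hyperparameters, 10-fold cross-validation), converts predictions into
    subject-level normative probability maps (Z scores with within-subject
    false-discovery-rate control), summarises cohorts through deviation
    overlap maps and mass-univariate case-control contrasts, scores each
    subject's most extreme deviations (trimmed top-1% |Z| with a Gumbel
    extreme-value fit and top-k cohort-enrichment tests), and relates
    deviation scores to symptom severity by rank correlation. Includes a
    seeded synthetic-cohort generator emulating the statistical structure
    of a heterogeneous cross-sectional autism study, so the whole pipeline
    is testable end to end without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
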