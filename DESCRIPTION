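Package: neuroSexDiff
Title: Sexual Differentiation of Functional Connectivity, Physiological
    Aging and Psychiatric Risk in Synthetic Adolescent Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study how regional sexual differentiation of
    functional brain connectivity relates to polygenic risk, pubertal
    maturation, physiological aging and psychiatric symptom change.
    Provides a synthetic-cohort generator with planted ground truth
    (sex-differentiated connectivity aligned to a sensorimotor-association
    gradient, a polygenic-risk to brain to physiology to symptom causal
    chain, and Gompertz survival data), functional-connectivity
    construction with nuisance regression and motion quality control,
    an adult reference template of sex-linked connectivity with per-region
    similarity scoring, a Gompertz mortality model inverted to a
    PhenoAge-style biological age, pubertal index construction,
    cross-validated canonical correlation and partial least squares
    analyses with permutation and bootstrap inference, serial mediation
    with heteroscedasticity-consistent errors and percentile bootstrap,
    and hemisphere-paired spin permutations for spatial null inference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    sandwich,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    survival,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
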