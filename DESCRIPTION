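Package: pcrscreen
Title: Predictive Biomarker Screening, Cutpoint Discovery and Bayesian
    Subgroup Estimation for Binary Trial Endpoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Biomarker analysis toolkit for two-arm neoadjuvant trials
    with a binary pathologic complete response endpoint: pre-specified
    logistic regression screens with likelihood-ratio tests (arm-wise,
    treatment-interaction and receptor-adjusted forms), a repeated
    cross-validation procedure selecting dichotomizing biomarker
    cutpoints by logit-method combined p-values with a training-set
    stability filter, Bayesian logistic subgroup models sampled by
    adaptive Metropolis MCMC with posterior pCR-rate estimates for
    biomarker-defined subsets, subtype-balanced resampling
    standardization of reverse phase protein array batches, a
    multi-caller somatic variant consensus filter, hypergeometric
    over-representation analysis with Benjamini-Hochberg correction,
    and a synthetic trial-cohort generator with known ground truth for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
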