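Package: fpmi
Title: Fractional Polynomial Model Building with Multiply Imputed Covariates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds fractional polynomial (FP) and multivariable fractional
    polynomial (MFP) regression models when continuous covariates are
    partially observed.  Provides the complete-data function selection
    procedure for Gaussian and logistic models, an approximate-Bayesian-
    bootstrap imputation algorithm that propagates uncertainty in the FP
    exponent through chained-equations multiple imputation, exponent
    estimation and closed-test model selection on multiply imputed data via
    stacked weighted likelihood-ratio tests and pooled Wald / delta-Wald
    tests, and a simulation harness for type-I-error and power studies under
    MCAR and MAR missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
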