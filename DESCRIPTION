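Package: polymr
Title: Polynomial Mendelian Randomization for Non-Linear Causal Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of non-linear (polynomial) causal effects of a
    continuous exposure on a continuous outcome from individual-level
    genotype data, using a two-stage least-squares control-function
    approach with a polynomial control function. Includes backward
    elimination of non-significant exposure powers with Bonferroni
    correction, a likelihood-ratio test for non-linearity, causally
    explained variance, 95% confidence hulls for the causal curve, a
    reverse-causation instrument filter, a genotype-phenotype simulator
    with realistic allele-frequency-dependent genetic architectures, and
    a replicate evaluation harness (bias, RMSE, confidence-interval
    calibration, polynomial-order detection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    data.table,
    yaml,
    optparse
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
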