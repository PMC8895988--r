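Package: phenopred
Title: Genomic and Phenomic Prediction for Structured Breeding Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mixed-model analysis of multi-environment plant-breeding trials
    and ridge-regression best linear unbiased prediction (RR-BLUP) from
    either SNP markers or near-infrared reflectance spectra. Provides plot
    level outlier screening, REML variance components, best linear unbiased
    estimates and entry-mean heritabilities; stepwise SNP quality control
    with per-group minor-allele-frequency filters, naive imputation and
    predictor-matrix merging; Savitzky-Golay spectral preprocessing with
    per-wavelength mixed-model estimates; a predictor-agnostic RR-BLUP core
    with its kernel (GBLUP) equivalence; cross-validation, among-group and
    composite-training-set evaluation designs with an overall versus
    within-subgroup correlation decomposition and DAPC group
    discrimination; and a synthetic-data generator emulating structured
    maize panels so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    MASS,
    Matrix,
    stats,
    utils
Suggests:
    jsonlite,
    signal,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
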