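Package: mfaflow
Title: Quantification of Platelet Accumulation in Microfluidic Flow Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for microfluidic flow assays (MFAs) of platelet
    accumulation on immobilized collagen. Converts time-lapse fluorescence
    image stacks into percent platelet surface coverage using triangle
    (Zack) histogram thresholding and small-object removal, reduces coverage
    curves to end-point surface coverage, lag time and accumulation velocity
    (robust bisquare regression), computes rectangular-microchannel
    hemodynamics (wall shear rate, syringe bank design, Fahraeus and
    Fahraeus-Lindqvist corrections via the Pries in vitro relations),
    simulates synthetic donor cohorts and low signal-to-noise image stacks
    with known ground truth, and runs the cohort association test battery
    (Spearman, Mann-Whitney, Kruskal-Wallis with Tukey HSD, two-way ANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    tiff,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
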