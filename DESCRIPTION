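Package: mdrquant
Title: Automated Quantification of Mammographic Dense Rate from MLO Mammograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully automated pipeline for quantifying the mammographic dense
    rate (MDR) on processed mediolateral-oblique (MLO) mammograms. Provides a
    seeded synthetic-phantom generator with pixel-level ground-truth masks, a
    U-Net style encoder-decoder semantic segmenter (pectoral muscle, gland,
    fat) implemented in 'RcppArmadillo' with DICE-coefficient evaluation,
    pectoral-referenced dense-pixel thresholding with breast-composition
    atlas categories, and age-stratified cohort analytics (per-age summary
    statistics, mean-median divergence, moving-average temporal
    differentiation, MDR histograms, and individual-trajectory
    classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
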