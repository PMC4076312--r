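Package: lateralize
Title: Bootstrap Laterality Indices, Gaussian Mixture Typing, and
    Handedness Concordance for Functional Lateralization Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for studying hemispheric functional lateralization of
    language from task fMRI t-statistic maps. Computes a bootstrap
    hemispheric functional lateralization index (HFLI) from suprathreshold
    voxel values per hemisphere, fits univariate Gaussian mixtures to HFLI
    samples by maximum-likelihood EM with corrected-AIC (AICc) model
    selection, derives lateralization types (Typical, Ambilateral,
    Strongly-atypical) from local minima of the fitted mixture density,
    and quantifies the handedness/language-dominance relationship with
    chance-corrected kappa, Fisher exact tests, Spearman correlation and
    an atypical-occurrence regression on Edinburgh handedness categories.
    Includes a seeded synthetic-data generator (cohorts, HFLI samples,
    lateralized t-maps) so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    e1071,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
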