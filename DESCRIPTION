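Package: plexda
Title: Differential Abundance Analysis for Multiplexed Labeled Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential abundance workflows for isobarically labeled
    (TMT-style) mass-spectrometry proteomics with arbitrarily complex
    designs. Provides a linked multi-level assay container for PSM- and
    protein-level reporter intensities, preprocessing (log2 transformation,
    channel-median and reference normalization, spike-in style filters),
    Tukey median-polish and median-sweep protein summarization, per-protein
    robust ridge linear mixed models estimated by REML with Huber
    M-estimation, empirical-Bayes variance moderation, Wald tests on
    arbitrary contrasts with Benjamini-Hochberg control, an automatic model
    reduction fallback for one-hit-wonder proteins, a hierarchical spike-in
    simulator, and spike-in benchmark metrics (TPR-FDP curves).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    limma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
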