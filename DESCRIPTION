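Package: segmorph
Title: Larval Segment-Position Morphometrics and Phylogenetic Comparative Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement and comparative analysis of relative larval segment
    position in Drosophila. Detects denticle-belt borders in dark-field larval
    images, converts them to relative positions (fraction of body length),
    summarises species differences with interaction ANOVA, Tukey HSD and
    Bonferroni-corrected pairwise tests, end-removal renormalisations, PCA and
    within-species correlation profiles, and fits a multivariate Brownian-motion
    model of segment-position evolution on a fixed ultrametric phylogeny by
    MCMC, with strict and relaxed (uncorrelated and autocorrelated lognormal)
    branch-rate clocks, ancestral-state reconstruction, per-branch normalised
    change, between-segment rate correlations, and stepping-stone marginal
    likelihoods. A synthetic-data module generates trees, trait histories,
    individual-level cohorts and ground-truthed dark-field images so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    broom,
    optparse,
    phytools,
    png,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
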