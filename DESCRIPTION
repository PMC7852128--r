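Package: microtide
Title: Tidy Microbiome Count-Table Pipeline with Per-Taxon Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Merges OTU count tables with clinical metadata into a tidy long
    format and carries that single data frame through a complete amplicon
    analysis: centered log-ratio transforms with a 1/depth pseudocount,
    prevalence/abundance taxa filtering into an "Other" category, bootstrapped
    rarefaction alpha diversity with coverage gating, Bray-Curtis and related
    dissimilarities with PERMANOVA, PCA/PCoA ordination including three-mode
    variants for repeated measures, per-taxon negative binomial and
    beta-binomial regression with profile-likelihood intervals, rank-based
    fallbacks for non-converged taxa, FDR-adjusted estimate tables, and the
    plot data behind stacked bars, Rocky Mountain plots, correlation heatmaps
    and forest plots. Includes a Dirichlet-multinomial simulator with known
    ground truth and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    MASS,
    glmmTMB,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
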