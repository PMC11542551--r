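Package: statefluct
Title: Fluctuation Analysis of Heritable Infection Susceptibility in Clonal Cell Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Luria-Delbruck style fluctuation analysis of adenovirus infection
    susceptibility in clonal human epithelial cell populations. Calls per-well
    infection indices from per-nucleus GFP reporter intensities using an
    uninfected-control percentile cutoff, decomposes infection-index variability
    into technical and biological coefficients of variation compared with the
    paired Wilcoxon signed-rank test, and quantifies the persistence ("memory")
    of population-specific susceptibility through technical, biological (A/B
    replicate-split) and permutation-baseline correlations over weekly
    timepoints. A hierarchical synthetic-data generator (heritable latent
    log-odds susceptibility with AR(1) or two-state Markov dynamics, well-level
    technical noise, cell-level Bernoulli infection, log-normal reporter
    intensities) emulates the high-content microscopy study design, and an
    optional imaging module renders synthetic two-channel fields and re-extracts
    measurements so the table-level pipeline can be exercised from pixels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
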