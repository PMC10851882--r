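Package: nutprior
Title: National Nutrient-Reduction Conservation Prioritization for Subwatersheds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes agricultural nitrogen and phosphorus budgets (surplus and
    nutrient use efficiency) from component fluxes at the HUC8 subwatershed
    scale, derives watershed landscape metrics from land-cover grids (tile
    drainage fractional cover, zonal percentages), classifies subwatersheds
    into in-field and edge-of-field conservation-strategy classes with a
    five-step threshold decision tree, and produces national and river-basin
    summary products (strategy tallies, net-surplus shares, Spearman
    correlation matrices, median/IQR tables). Includes a seeded
    Gaussian-copula generator of synthetic subwatershed tables calibrated to
    published rank-correlation structure and quantile anchors, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    stats,
    Matrix,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
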