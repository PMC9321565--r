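Package: grasscc
Title: Grassland Carrying Capacity and Relative Stocking Density from
    Gridded Productivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A raster pipeline for estimating livestock carrying capacity on
    grasslands from gridded annual net primary productivity. Partitions NPP
    to aboveground biomass with a temperature-dependent allocation model,
    restricts forage by tree-canopy cover and terrain slope, converts biomass
    to an animal-unit carrying capacity, and compares it against
    species-resolved livestock headcounts as a relative stocking density with
    proper-use-factor class boundaries. Includes Monte Carlo propagation of
    parameter uncertainty (truncated-normal and uniform specifications),
    per-pixel linear trend and Kendall rank-trend analytics, interannual
    variability statistics, zonal aggregation, and a synthetic-scenario
    generator so the whole chain is testable at desk scale without external
    satellite or census data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
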