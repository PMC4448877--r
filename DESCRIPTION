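Package: ballastr
Title: Hindcasting Ballast Water Discharge and Propagule Pressure over
    Shipping Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models per-voyage ballast water discharge from vessel geometry
    and destination port purpose, hindcasts discharge over a shipping
    network, converts discharge into propagule pressure with an
    exponential-decay survival model that accounts for mid-ocean ballast
    water exchange, and ranks routes and marine ecoregions by invasion
    risk. Includes a deadweight-tonnage formula reverse-engineered from
    ship-design guidelines, an EM fitter for mixtures of linear
    regressions with AIC/AIC3/MDL/BIC component selection, over-water
    shortest-path routing on a visibility graph, and a synthetic
    shipping-world generator with known ground truth for offline testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
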