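Package: streamvuln
Title: Climate-Change Vulnerability Assessment for Freshwater Species on
    Stream Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the vulnerability of freshwater species to climate
    change from habitat-suitability surfaces projected over a subcatchment
    stream network. Implements exposure (standard-deviation departure of
    future conditions over current habitat, plus a sea-level rule),
    sensitivity (the ratio of lost to remaining thresholded suitability),
    and dispersal pressure (least-cost-path distances through a
    four-parameter logistic kernel, a habitat-shift rank-sum test and a
    threshold-sweep slope score), combines them into vulnerability
    categories, compares dispersal-barrier scenarios, and builds
    sensitivity-weighted conservation priority maps. Includes a synthetic
    landscape and species generator so the whole pipeline is testable
    without proprietary continental data, a TSS-weighted ensemble wrapper
    around a pluggable suitability scorer, and plain-text GeoJSON / ESRI
    ASCII / CSV input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
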