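Package: greenview
Title: Street Greenery Assessment from Street-Level Imagery via the Green View Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automatic framework for quantifying visible street greenery in
    cities. Street centerlines are simplified (divided roads merged, dangles and
    pseudo-nodes removed), sample sites are placed every 50 m along segments, and
    four directional street-level photographs per site are acquired through a
    pluggable provider interface (live panorama API, local directory, or a fully
    synthetic mock). Each photograph's Green View Index (GVI) -- the fraction of
    pixels whose HSV hue falls in a green range, 60-180 degrees by default -- is
    computed from a 360-bin hue histogram, averaged per site, and aggregated to
    street segments and to blocks delineated by subtracting class-dependent
    street buffers from the study area. City-level summaries include a
    mean/spread typology, global Moran's I spatial autocorrelation, and
    standardized OLS regressions of location-level GVI on street- and city-level
    covariates, with backward elimination by administrative level. Synthetic
    scene, street-network and regression-panel generators with known ground
    truth make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
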