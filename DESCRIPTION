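Package: sarplan
Title: Cost-Benefit Optimization of Ecological Restoration Site Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatially explicit prioritization of habitat restoration sites.
    Per-pixel biodiversity benefits are computed from a modified
    species-area relationship (reduction in extinction risk per restored
    pixel), optionally weighted by dispersal distance to the current range
    and by climate suitability, aggregated across species, and divided by
    per-pixel land-acquisition cost. Sites are then selected by exactly
    maximizing the summed benefit/cost ratio under a total-area cap and
    per-habitat-type minimum-area constraints, iterated to capture
    diminishing returns as restored area accrues. Includes a seeded
    synthetic-landscape generator (banded habitat mosaic, autocorrelated
    lognormal land values, nested species ranges, smooth suitability
    surfaces) so the full pipeline runs without external data, plain-text
    raster (Esri ASCII grid) and GeoJSON range I/O, scenario reports, and
    tidy/ggplot2 accessors for all results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
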