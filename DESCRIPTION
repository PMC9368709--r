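Package: tideflux
Title: Land-Sea Material Exchange Evaluation for Intertidal Wetlands
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Raster pipeline for evaluating the land-sea material exchange
    function of intertidal wetlands. Composes per-cell Manning roughness from
    base-soil, micro-topography and vegetation contributions; propagates a
    sea-seeded exchange capacity across the grid by max-product attenuation;
    computes a log-ratio exchange-function index against a reference year; and
    summarises results zonally by vegetation type. Includes a synthetic
    zoned-wetland scene generator emulating a Spartina alterniflora invasion
    so every stage is testable without satellite data, plus brute-force and
    shortest-path oracles for the propagation step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
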