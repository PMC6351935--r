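Package: sparaccess
Title: Multimodal Spatial Accessibility to Primary Care with Floating
    Catchment Areas and Spatial Access Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for measuring spatial accessibility to primary healthcare
    by driving, walking, and multimodal (walking plus bus and light rail)
    travel. Builds travel-time networks from vector street, sidewalk, and
    transit layers (including geometric generation of crosswalks from
    road-intersection buffers), computes Enhanced Two-Step Floating Catchment
    Area (E2SFCA) accessibility with three-zone distance decay, normalizes
    indices to Spatial Access Ratios (SPAR), identifies physician shortage
    areas, and relates accessibility to area-level deprivation covariates via
    Moran's I permutation tests and maximum-likelihood spatial-lag
    regression. A seeded synthetic-city generator exercises the full
    pipeline without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
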