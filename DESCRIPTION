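Package: kbascope
Title: IUCN Criterion B Range Metrics, Area of Habitat, and Key
    Biodiversity Area Scoping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatial conservation assessment toolkit for single-species
    IUCN Red List criterion B evaluations and Key Biodiversity Area (KBA)
    scoping. Computes extent of occurrence (minimum convex polygon in an
    equal-area projection), area of occupancy on the standard 2 x 2 km
    grid, and distance-clustered locality counts; classifies the species
    under the criterion B threshold table; builds Area of Habitat (AOH)
    maps by masking categorical land cover with an occurrence-derived
    elevation band; validates AOH maps against occurrence points with an
    upper-tail hypergeometric test; scopes potential KBAs on a 10 x 10 km
    grid using habitat area as the population-size proxy; and measures
    protected-area coverage of the scoped sites. A synthetic island
    landscape generator (smoothed random fields, habitat-conditioned
    occurrence sampling, contour-delineated protected areas) makes the
    whole pipeline runnable and testable without external geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
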