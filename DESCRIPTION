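Package: vegsucc
Title: Grid-Based Simulation of Herbaceous Vegetation Succession Driven by
    Ecological Indicator Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A raster-based simulator of herbaceous vegetation dynamics in
    semi-natural landscapes. Per-species cover compartments in each grid cell
    grow, die back and compete for free space under environmental control
    functions that match species-level Ellenberg indicator values (light,
    temperature, moisture, soil reaction, nutrients) and Briemle land-use
    tolerance values (cutting, grazing, trampling) against cell-level site
    values.  Vegetative spread into the eight-cell neighbourhood is
    stochastic, community composition is aggregated into vegetation types by
    an ordered decision tree, and the two free species parameters (maximum
    growth rate and self-regulation factor) can be calibrated against target
    equilibrium communities.  Includes readers and writers for delimited
    parameter tables and ESRI ASCII grids, tools to derive site indicator
    values from vegetation releves or soil-map attributes, two fully
    parameterised demonstration landscapes and a command-line entry point.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
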