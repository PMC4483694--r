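Package: fugrisk
Title: Multimedia Fugacity Modelling and Multi-Pathway Cancer Risk Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dynamic (Level IV) four-compartment multimedia fugacity modelling
    of a persistent organic pollutant (air, water, soil, sediment) under daily
    time-varying emissions and meteorology, with a steady-state (Level III)
    solver as an internal oracle.  Fugacities feed a four-pathway human
    exposure model (food, tap water, inhalation, dermal contact) and a linear
    cancer-risk characterization based on slope factors and unit risks.
    Includes one-at-a-time relative sensitivity analysis, Monte Carlo
    uncertainty propagation with triangular distributions, a multi-region
    linked box model with wind-direction-dependent air advection, and a
    synthetic scenario generator packaged with a reconstructed benzo[a]pyrene
    case study for an industrializing city.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
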