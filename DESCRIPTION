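Package: skinpampa
Title: Skin-PAMPA Plate Reduction, Permeability Coefficients and Permeate
    Classification
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reduces parallel artificial membrane permeability assay (PAMPA)
    plate data to membrane retention factors, permeation parameters and
    effective permeability coefficients (log Pe), predicts human skin
    permeability (log Kp) from log Pe with a published linear regression,
    and classifies compounds into permeate groups I-III from their
    retention/permeation profile. Includes a two-compartment kinetic
    simulator with lag time, membrane retention and multiplicative HPLC
    peak-area noise, so the whole pipeline is testable against known ground
    truth, plus a packaged 26-compound corticosteroid reference table and a
    command-line interface for batch use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
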