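Package: cdpbpk
Title: Physiologically Based Pharmacokinetic Modelling of Chlordecone in
    Rats and Humans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A seven-compartment physiologically based pharmacokinetic
    (PBPK) simulator for the organochlorine insecticide chlordecone
    (Kepone) in rats and humans.  The model describes permeability-limited
    tissue distribution, blood and saturable hepatic protein binding,
    lymphatic and portal uptake from the gut, biliary excretion with
    enterohepatic recirculation, hepatic reduction to chlordecone alcohol
    (humans only), and enteric and urinary elimination.  Utilities cover
    forward dosimetry under oral, dietary and intravenous exposure
    scenarios, reverse dosimetry from steady-state blood concentrations,
    terminal half-life and excretion-fraction summaries, local one-at-a-time
    sensitivity screening, relative-error likelihood calibration, and
    generation of synthetic observation sets emulating classical
    toxicokinetic study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
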