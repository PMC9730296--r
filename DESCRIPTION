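Package: dropkin
Title: Droplet-on-Demand Absorbance Kinetics: Instrument Simulation and
    Michaelis-Menten Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physics-based simulator and analysis pipeline for multiplexed
    droplet-on-demand absorbance enzymology. Simulates the formation of a
    substrate concentration gradient in a stirred microtiter well under
    simultaneous injection and withdrawal, the resulting droplet train, the
    in-droplet enzymatic reaction, and the multi-channel transmitted-light
    trace recorded by a line camera across repeated flow reversals. The
    analysis side segments raw traces into droplets, tracks each droplet
    across passes, calibrates absorbance against a known product train,
    assigns per-droplet substrate and enzyme concentrations from the fluidic
    parameters, extracts initial rates, and fits Michaelis-Menten parameters
    per detection point with cross-channel aggregation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
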