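Package: relaxex
Title: Proton-Exchange Models for Low-Field NMR Relaxation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models biexponential proton NMR relaxation in aqueous
    carbohydrate solutions as the consequence of second-order (bimolecular)
    chemical exchange between solvent and solute hydroxyl protons, rather
    than distinct "bound" and "free" water pools. Provides closed-form
    solutions of the exchange-coupled longitudinal and transverse
    magnetization equations with concentration-dependent rate coefficients,
    their fast-exchange asymptotics, stoichiometric proton inventories for
    protiated and deuterated sucrose-water preparations, mono- and
    biexponential fitting of saturation-recovery and CPMG decays with
    model selection and uncertainty, a synthetic time-domain NMR data
    generator, and command-line pipelines for inventory tables, eigenrate
    sweeps and fit-and-compare runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
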