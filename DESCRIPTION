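Package: aqpflux
Title: Stopped-Flow Permeability Kinetics and pH-Gating Analysis for
    Aquaglyceroporins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates osmotic water permeability (Pf) and glycerol
    permeability (PGly) of membrane channels from stopped-flow
    fluorescence traces via a kinetic cell-volume model, derives gating
    statistics (Hill pKa, Arrhenius activation energy, dose-response
    IC50, percent inhibition, relative membrane expression), and
    post-processes molecular-dynamics coordinate streams for channel
    crossing counts and the single-file water diffusion constant.
    Includes seeded synthetic-data generators emulating shrink/reswell
    stopped-flow assays with photobleaching drift for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
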