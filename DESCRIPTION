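Package: afmindent
Title: Elastoviscoplastic Analysis of AFM Nanoindentation Force Curves
Version: 0.1.0
Authors@R:
    person("AFM Indent", "Maintainers", email = "maintainers@afmindent.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for atomic force microscope (AFM)
    nanoindentation of stiff biological cells such as corneocytes.
    Calibrates an effective axisymmetric indenter geometry a(h_c) from
    force curves on a linear-elastic reference elastomer via Sneddon
    contact mechanics for power-law indenters, then extracts Young's
    modulus and hardness from Oliver-Pharr style unloading analysis,
    Prony-series hardness relaxation from constant-height holds, and
    Herschel-Bulkley viscoplastic parameters (yield stress, flow
    consistency, flow index) from the paired stress / plastic
    strain-rate decay.  Includes a forward simulator of loading-pause-
    unloading force curves so that every stage of the pipeline can be
    validated by parameter recovery without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
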