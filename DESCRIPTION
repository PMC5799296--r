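Package: tdp43nar
Title: Negative Autoregulation and Aggregation Dynamics of TDP-43
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compartmental kinetic model of intracellular TDP-43 metabolism:
    Hill-repression negative autoregulation (NAR) of canonical TARDBP mRNA
    production via nonsense-mediated decay of alternatively spliced isoforms,
    nuclear/cytoplasmic protein shuttling, concentration-dependent
    fragmentation, and fragment-seeded cooperative aggregation. Provides a
    calibration routine that reconstructs rate constants from published
    steady-state constraints (NMD flux fraction, cytoplasmic/nuclear ratio,
    degradation-rate ratios, protein half-life), a stiff ODE simulation layer
    with perturbation schedules, a scenario suite (heterozygous knockout,
    transgene dose response, parameter sweeps, transcriptional-redundancy
    staging, transcription-reduction therapy, extracellular fragment
    propagation), bistability and hysteresis analysis, healthy/disease state
    classification, transcriptional-redundancy estimators, and SBML Level 3
    model exchange.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    xml2,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
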