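Package: mmpathways
Title: Treatment-Pathway Reconstruction and Disease-Progression Modelling
    from Administrative Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs multiple-myeloma treatment pathways from
    patient-level administrative claims: cohort selection with auditable
    exclusion logging, line-of-therapy construction from dispensing claims
    using gap and regimen-addition rules, regimen classification,
    Charlson/Deyo comorbidity scoring, an empirical Markov
    disease-progression model over treatment lines with Sankey export, and
    privacy-suppressed summary tables. Ships a synthetic claims generator
    with serialized ground truth so every stage is testable without access
    to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
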