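Package: glycoHFPN
Title: Hybrid Functional Petri Net Simulation of Glucose and Glycogen
    Utilization in Escherichia coli
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A fixed-step hybrid functional Petri net (HFPN) engine and an
    integrated kinetic model of Escherichia coli carbohydrate metabolism:
    glycolysis and the pentose phosphate pathway, the phosphoenolpyruvate:sugar
    phosphotransferase system (PTS) phospho-relay, glycogen synthesis and
    phosphorolysis, and the regulatory circuit centred on HPr and EIIA(Glc)
    (FDP/Cra, phosphorylated-EIIA/cAMP/CRP, HPr subcellular localization, and a
    multi-valued glycogen-composition switch). Includes batch-culture phase
    classification into the five canonical growth phases, qualitative
    regulator-state tables, Pearson correlation model evaluation against
    observed time courses, a synthetic observation generator, and least-squares
    parameter fitting with recovery diagnostics.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    xml2,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
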