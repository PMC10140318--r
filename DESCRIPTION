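Package: probioflow
Title: Automated Flow-Cytometry Gating and Fermentation Analytics for
    Probiotic Lactic Acid Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for oxygen-level cultivation studies of
    probiotic lactic acid bacteria such as Limosilactobacillus reuteri.
    Gates online flow-cytometry event data (SYBR Green I / propidium
    iodide staining, FL1-H/FL3-H channels) into viability subpopulations
    by multi-restart spherical k-means or fixed linear gates; computes
    batch-fermentation kinetics (maximum specific growth rate, product
    yields, specific rates, end-point carbon balance, dissolved-oxygen
    depletion time); summarises membrane fatty-acid methyl ester (FAME)
    composition including the UFA:SFA ratio with propagated standard
    deviations; and quantifies probiotic functionality markers
    (freeze-drying survivability, acid-challenge death kinetics,
    bile-tolerance lag time, 5'-nucleotidase activity). A seeded
    synthetic-data generator emulates every input so the full pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
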