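Package: tftitrate
Title: Quantitative Analysis of Titratable Transcription-Factor Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative analysis of titratable
    transcription-factor (TF) expression libraries in bacteria:
    fluorescence-to-copy-number calibration from binomial partitioning of
    fluorophores between daughter cells, evaluation and fitting of the
    thermodynamic fold-change model of gene regulation (binding-energy and
    maximal fold-change inference, paralog comparison), a kinetic ODE model
    of metal-responsive regulation by a MerR-family TF (ZntR/zinc/ZntA),
    and growth-rate extraction and phenotype clustering from plate-reader
    optical-density time series. Includes seeded synthetic-data generators
    for every input table so the full pipeline is testable without
    microscopy or plate-reader data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rlang,
    stats,
    utils,
    tools,
    deSolve,
    jsonlite,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
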