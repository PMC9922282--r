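Package: hrfassay
Title: Protection-Factor Footprinting and Enzyme Assay Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for hydroxyl radical protein footprinting
    (HRF): converts integrated mass-spectrometry peak areas into per-site
    first-order modification rate constants and protection factors,
    compares protection between liganded and unliganded states, and maps
    differential protection onto a protein structure. Also implements the
    companion biophysical assays used to characterise an enzyme and its
    inhibitors: thermal-shift melting temperature extraction from
    dye-fluorescence melt curves, Michaelis-Menten/Hill kinetics from
    initial-rate titrations, and three-parameter logistic IC50 fitting.
    Ships a synthetic-data module emulating each assay's statistical
    structure so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    dplyr,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
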