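Package: paoshift
Title: Polyphosphate Accounting, Anaerobic Cycle Kinetics and the
    Poly-P/Glycogen Metabolic Shift in Enriched PAO Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of enhanced biological
    phosphorus removal (EBPR) enrichment cultures of polyphosphate-
    accumulating organisms (PAO) run in sequencing batch reactors (SBR).
    Characterizes influent media from chemical recipes (molar carbon,
    nitrogen, phosphorus, theoretical COD, P/C ratio), estimates biomass
    polyphosphate by two independent routes (inorganic-solids based and
    steady-state phosphorus mass balance) with cross-validation, accounts
    active biomass and storage-polymer ratios on gVSS and C-mol bases,
    extracts anaerobic kinetic rates and stoichiometric ratios from SBR
    cycle tests, quantifies the shift between glycogen-dominated and
    poly-P-dominated anaerobic metabolism as an ATP-source partition and a
    two-end-member mixing model with carbon and electron balance checks,
    and generates synthetic SBR data with known ground truth so the whole
    pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
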