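Package: qamskit
Title: Single-Marker Quantification (QAMS) for Multi-Analyte HPLC-DAD Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of multicomponents by single
    marker (QAMS) in chromatographic assays: per-analyte linear calibration
    with limits of detection and quantification, external-standard
    quantification of extract contents, relative correction factors across
    injection volumes, instruments and columns, single-marker quantification
    and its accuracy against the external-standard method, and the standard
    method-validation battery (precision, repeatability, stability, spike
    recovery). Ships a synthetic chromatogram and peak-table generator with
    known ground truth, modelled on a nine-flavonoid Psoralea corylifolia
    seed assay, so the whole pipeline is testable without an instrument.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
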