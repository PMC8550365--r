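Package: ramanci
Title: Raman Spectroscopy Crystallinity of Microcrystalline Cellulose
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying the crystallinity index (%CI) of
    microcrystalline cellulose from Raman spectra.  Implements anchor-point
    baseline correction and standard normal variate normalization, the
    amorphous-subtraction 380/1096 cm-1 band-ratio method with
    instrument-specific linear calibration against powder X-ray diffraction
    (Segal peak-height) crystallinity, NIPALS principal component analysis
    and PLS1 regression with batch-grouped segmented cross-validation, and a
    synthetic Raman spectrum and diffractogram generator with known
    crystalline fraction so that every stage of the pipeline can be
    validated end to end without instrument data.
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
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
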