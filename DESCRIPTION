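Package: paoxim
Title: Photoacoustic Oximetry Analysis for Photodynamic Therapy Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for real-time ultrasound-guided photoacoustic
    monitoring of tumor blood oxygenation during photodynamic therapy (PDT).
    Converts interleaved two-wavelength (750/850 nm) photoacoustic frame
    stacks into oxygen saturation (StO2) and total hemoglobin (HbT) maps by
    closed-form non-negative spectral unmixing, masks sub-noise-floor pixels
    using corner reference patches, extracts region-of-interest kinetic
    traces (median filtering, baseline normalization, moving-slope depletion
    rates, end-of-active-PDT detection), builds milestone difference maps of
    StO2 change, and compares treatment-group depletion rates by one-way
    ANOVA with Tukey contrasts. Includes a synthetic tumor-phantom generator
    of fluence-rate-dependent PDT oxygen dynamics so every pipeline stage is
    testable without animal data, plus the Severinghaus oxygen dissociation
    curve and light-dose arithmetic utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
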