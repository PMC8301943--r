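Package: mipadt
Title: Active Dynamic Thermography Analysis for Trigger-Point Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Automated analysis of active dynamic thermography recordings
    from the minimally invasive procedure (MIP) used to screen sciatica
    patients for myofascial trigger points. Reads per-frame temperature
    matrices and painted BMP region-of-interest masks, converts masks to
    binary ROI matrices, computes the two diagnostic parameters -- the
    autonomic referred pain area percentages (AURP up/down) and the change
    in mean ROI temperature (delta Tavr) -- as time series per anatomical
    region, applies the recording-quality cleaning rules, and compares
    trigger-point-positive and -negative groups per timepoint with exact
    tie-corrected Mann-Whitney U tests and Firth bias-reduced logistic
    regression. A synthetic-cohort generator with planted vasodilatation
    dynamics supports end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
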