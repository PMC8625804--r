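Package: hrmscan
Title: High-Resolution Melting Variant Scanning with Melting-Domain Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of high-resolution melting (HRM) curves for variant
    scanning. Reads instrument melt-curve exports, detects melting domains
    from Savitzky-Golay derivatives of the fluorescence trace, normalizes
    each domain's melting region with two-baseline background subtraction,
    compares samples against a median/SD reference band built from control
    curves, and calls samples variant or normal. Includes sex-stratified
    and per-domain analysis for long amplicons, support for artificial
    heterozygote (mixed) preparations, and a synthetic melt-curve simulator
    with known ground truth for validating the whole pipeline without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
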