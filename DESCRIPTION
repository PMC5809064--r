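Package: epidivd
Title: EPID-Based In Vivo Dosimetry Evaluation for Radiotherapy QA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to evaluate electronic portal imaging device (EPID) based
    in vivo dosimetry for intensity-modulated and volumetric-modulated arc
    radiotherapy. Implements the two per-beam test indices -- the isocentre
    dose ratio R reconstructed from the transit signal by a mid-plane
    backprojection model, and a global 2D gamma analysis of portal images
    with site-specific criteria -- together with tolerance and warning
    logic, acquisition-artifact exclusion, two-stage per-patient averaging,
    and cohort aggregation into per-site test and patient pass-rate tables.
    A forward simulator generates synthetic transit images and full cohort
    index tables with known injected error classes (setup errors,
    morphological changes, acquisition artifacts), and readers and writers
    handle per-beam index record tables in CSV and XLSX form.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    yaml,
    xml2,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
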