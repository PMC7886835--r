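Package: fluorodose
Title: Monte Carlo Skin and Room Dosimetry for Fluoroscopically Guided Procedures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for real-time radiation dose awareness in the
    interventional radiology suite. Simulates keV photon transport through
    CT-derived voxel phantoms with Woodcock (delta) tracking to map patient
    skin dose, scores scattered air kerma on a room lattice, precomputes an
    angular air-dose lookup table over the C-arm gantry range and converts
    interpolated air kerma at a tracked head position to eye-lens dose with
    the ICRP scalar factor. Includes a fluoroscopic-condition acquisition
    pipeline (template-matching digit recognition of console displays and
    temperature-corrected ultrasonic table ranging) and a session
    orchestrator that emits hologram-ready dose payloads as JSONL.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    jsonlite,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
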