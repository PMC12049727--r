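Package: lamellometer
Title: Thickness and Quality Control for Cryo-FIB Lamella Fabrication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calibration-free thickness determination for frozen-hydrated,
    focused-ion-beam-milled lamellae. Implements geometric wedge estimation
    from reflected light microscopy, thin-film interference reflectivity
    fitting for per-pixel thickness maps, quantitative 4D-STEM thickness
    measurement backed by a Monte-Carlo electron scattering lookup table,
    energy-filtered TEM zero-loss log-ratio mapping for benchmarking, and
    axial targeting corrections under refractive index mismatch. Synthetic
    data generators emulate every measurement modality with known ground
    truth so all pipelines are testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
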