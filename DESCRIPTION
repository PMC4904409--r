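Package: soarseg
Title: Segmentation and Performance Analysis of Soaring-Gliding Bird Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing high-frequency GPS and tri-axial
    accelerometer tracks of soaring-gliding birds. Segments 1-Hz flight
    tracks into thermal-soaring, gliding and linear-soaring modes using
    two-dimensional path self-intersection and vertical-speed trend rules,
    annotates tracks with gridded wind and turbulence fields, and computes
    flight-performance metrics: thermal climb rate, drift-compensated
    circling radius, wind-relative circling geometry, the Risk-Averse
    Flight Index (RAFI), soaring-gliding efficiency, overall dynamic body
    acceleration (ODBA), flapping proportion and daily path statistics.
    Includes an inferential layer (rank tests, ANCOVA, AICc polynomial
    model selection) for group comparisons, and a synthetic soaring-track
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
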