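Package: msrdose
Title: Reference Dosimetry of Machine-Specific Reference Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calibration chain for clinical reference dosimetry of
    radiotherapy machines that cannot establish conventional 10 x 10 cm
    reference conditions, such as robotic FFF units with circular
    collimators.  Reads water-tank scan curves (dose profiles and
    percent-depth-dose curves), folds measured profiles into radial
    off-axis-ratio functions, computes ionization-chamber
    volume-averaging corrections by grid integration over the sensitive
    volume, evaluates influence-quantity corrections and beam-quality
    correction factors under both the TG-51 (with addendum) and TRS-483
    formalisms, propagates standard uncertainties in quadrature, and
    compares calibration scenarios in terms of absorbed dose to water
    per monitor unit.  Includes a seeded synthetic-data generator for
    water-tank scans and electrometer readings so the full pipeline is
    testable without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
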