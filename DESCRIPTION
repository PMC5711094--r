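Package: linacqa
Title: Linac IMRT/VMAT Commissioning QA: MLC Tests, Film Dosimetry, Gamma
    Analysis and TG-119 Confidence Limits
Version: 0.1.0
Authors@R: person("QA", "Physics", email = "qa@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for commissioning-style quality assurance of
    linear-accelerator IMRT and VMAT delivery. Provides a 2D dose-plane data
    model with CSV-grid, DICOM RT Dose and 16-bit RGB TIFF readers; MLC
    picket-fence peak/FWHM analysis with sub-millimetre error detection;
    dose-rate/gantry-speed and leaf-speed/dose-rate strip tests with
    open-field-corrected readings; radiochromic-film dosimetry (optical
    density, cubic calibration, dose mapping, registration); 2D gamma-index
    evaluation at configurable dose/distance criteria; and TG-119
    confidence-limit statistics for point doses and gamma passing rates.
    A seeded synthetic-data module generates beam planes, picket-fence
    images, strip patterns, film calibration scans and per-case measurement
    tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
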