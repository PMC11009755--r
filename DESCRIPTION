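Package: procam
Title: Projector-Camera Calibration and Closed-Loop Targeted Illumination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Hardware-independent computational stack for projector-coupled
    microscopes that steer light onto living samples: scan-zone
    projector-camera calibration with hyper-parameter auto-tuning (border
    variable, scan-line breadth, grid-based magnification estimation),
    scratch-assay wound-edge detection and pattern projection, and a
    closed-loop scheduler that re-targets the leading wound edge as it
    migrates. Ships a virtual optical bench that simulates the
    projector-to-sample-to-camera light path and a healing epithelial
    monolayer with optional light-accelerated migration, so every stage is
    testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    grDevices,
    stats,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
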