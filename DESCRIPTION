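Package: csfscan
Title: Automated Cerebrospinal Fluid Cell Counting and Method Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for microchip-based automated
    counting of white and red blood cells in cerebrospinal fluid. Provides a
    ground-truthed synthetic generator of dual-fluorescence chip-field images,
    circle Hough transform cell detection with size filtering and
    background-corrected intensity measurement, quadrant gating of events with
    deterministic resolution of the double-positive overlap zone, and absolute
    concentration calculation for chip imaging, Neubauer chamber and
    bead-calibrated flow cytometry protocols. Includes the analytical
    validation statistics used to verify such counters (linearity, limit of
    blank, limit of detection, precision profiles) and paired method-comparison
    statistics (Pearson correlation, Passing-Bablok regression, Bland-Altman
    analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
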