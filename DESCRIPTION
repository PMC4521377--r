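Package: skars
Title: Quantification of Kinase Activity Relocation Sensors in Single Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing synthetic kinase activity relocation sensors
    (SKARS), fluorescent reporters that leave the nucleus when a MAP kinase
    phosphorylates their nuclear localization sequence. Provides a
    two-compartment kinetic model linking kinase activity to the
    nuclear-to-cytoplasmic sensor ratio (forward simulation, steady-state
    calibration, and inference of activity time courses by least-squares
    fitting), a ground-truthed generator of synthetic single-cell traces and
    multi-channel time-lapse images, image quantification (nucleus
    segmentation, seeded cell expansion, cytoplasm rings, centroid tracking,
    intensity extraction), single-cell trace statistics (quality control,
    basal-level normalization, initial and final response, responder
    classification, cell-cycle-marker quadrant analysis), and a deterministic
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
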