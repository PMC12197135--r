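Package: pneumoshift
Title: Retroperitoneal Landmark Displacement Under Insufflation and Repositioning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies displacement of retroperitoneal vascular and organ
    landmarks across CT scan conditions (intra-abdominal pressure levels and
    patient positions) using a registration-free surrogate statistic: the mean
    absolute change, over a bony reference matrix, of reference-to-target
    Euclidean distances. Reads 3D Slicer markups fiducial files (FCSV) and
    long-format landmark CSVs, builds pressure-effect and position-effect
    comparison tables, measures fiducial placement repeatability, and validates
    the surrogate against ground truth via least-squares rigid (Kabsch)
    registration on the bony frame. Includes a synthetic torso-landmark
    simulator with parametric insufflation and positioning deformations that
    carries exact ground-truth displacements.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
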