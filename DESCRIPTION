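Package: ctqa
Title: Rubric-Based No-Reference Quality Assessment for Chest CT Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision layer for automated no-reference image quality
    assessment of chest CT examinations. Combines four deterministic
    algorithms (pixel-threshold classification of tri-colour tracheal
    carina masks, detection-box tallying across image series, body
    centering by region measurement, and scan-baseline alignment by
    distance measurement) with a multi-task scoring rubric covering
    eight sub-parts (tracheal carina, bronchial beam, rib, scan
    baseline, body position, arms position, radiation protection,
    artifact) and binary acceptability decisions. Detection and
    segmentation backends are pluggable; a deterministic scripted mock
    backend and a synthetic fixture generator make the whole pipeline
    testable without trained models or patient data. Includes
    macro-averaged classification metrics and IoU-based greedy box
    matching for backend evaluation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, jsonlite, png, tiff, yaml
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
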