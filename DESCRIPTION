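Package: footmark
Title: Automatic Radiographic Assessment of Foot Collapse
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Landmark-based measurement of foot collapse on lateral
    weight-bearing foot radiographs. Implements a 61-point landmark scheme
    with text/JSON annotation I/O and DICOM pixel-spacing extraction, a
    spline-based geometry calculator for calcaneal tilt, cuboid height and
    Meary's angle, Meary's-angle severity grading, a synthetic foot-phantom
    generator (deformable landmark templates, observer panels, rendered
    pseudo-radiographs), a shape-constrained random-forest regression-voting
    landmark localizer with subject-grouped cross-validation, and the full
    agreement-statistics suite (point-to-point/point-to-curve errors, ICC(2,1)
    with variance components, bias mixed model, cluster-bootstrap Pearson
    correlation, within-observer-range rates).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ranger,
    png
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
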