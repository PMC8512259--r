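Package: gfkhar
Title: Geodesic Flow Kernel Domain Adaptation for Wrist-Worn Activity
    Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying heterogeneity in wrist-accelerometer human
    activity recognition and for correcting it with unsupervised domain
    adaptation.  The package simulates annotated multi-sensor accelerometer
    sessions with controllable cross-sensor, cross-subject and
    cross-scenario distribution shifts, extracts discrete-wavelet-transform
    time-frequency features from fixed-size windows, and implements the
    geodesic flow kernel (GFK) on the Grassmann manifold together with
    subspace-disagreement dimension selection and rank-of-domain (ROD)
    source selection.  A support vector machine consumes the geodesic
    kernel; paired experiment drivers compare the adapted classifier
    against a no-adaptation baseline across sensors, subjects and task
    scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
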