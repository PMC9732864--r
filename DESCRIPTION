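Package: ecoglesion
Title: Spatial Relationship Between MRI Lesions and Intraoperative ECoG Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to relate intraoperative electrocorticography (ioECoG)
    biomarker rates (interictal spikes, ripples, fast ripples) to the
    geometry of an MRI-visible epileptogenic lesion. Implements electrode
    localization on a triangulated cortical surface with extrapolation of
    hidden grid electrodes, three lesion-to-electrode distance models
    (Euclidean distance to the lesion edge, to its centre of mass, and a
    geodesic distance along the cortical surface), per-channel biomarker
    rates from timestamped event logs in one-minute epochs,
    pathology-stratified linear regression with HC3 heteroscedasticity
    consistent standard errors and percentile-bootstrap confidence
    intervals, Welch's one-way ANOVA, binary logistic models for fast
    ripple occurrence, and simple-slopes moderation analysis with
    categorical (pathology type) and continuous (lesion volume)
    moderators. A seedable synthetic-cohort generator emulates surfaces,
    lesion masks, electrode arrays and event logs with realistic rate
    scales and distance-rate slopes so that the full pipeline can be
    exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    car,
    optparse,
    yaml
Config/testthat/edition: 3
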