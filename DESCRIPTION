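Package: mewdssf
Title: Structure-Function Analysis of Photoreceptor Recovery in MEWDS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal structure-function analysis of multiple
    evanescent white dot syndrome (MEWDS): photoreceptor reflectivity ratio
    (PRR) mapping from layered OCT raster volumes, microperimetry simulation
    and summaries (4-2 staircase thresholds, retinal threshold sensitivity,
    bivariate contour ellipse area fixation statistics), affine co-registration
    of microperimetry stimuli with the OCT en-face frame, and hierarchical
    (Hood-Kardon) and longitudinal mixed-effects models of retinal
    sensitivity. Includes a synthetic cohort generator that emulates the
    statistical structure of a MEWDS cohort (lesioned sensitivity fields,
    centrifugal recovery, foveal granularity, fixation dispersion, acuity
    coupling) so the full pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    withr,
    tiff
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
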