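Package: wristcal
Title: Calibration and Validation of Wrist-Cuff Blood Pressure Devices Against Intra-Arterial Reference Pressures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing and improving the agreement of noninvasive
    oscillometric blood pressure devices with simultaneously recorded
    intra-arterial (radial and ascending aortic) reference pressures.
    Provides a seeded synthetic-data generator for patient cohorts,
    beat-to-beat pressure series and device readings; encoding of a two-day
    measurement protocol with eligibility screening and assembly of
    simultaneous wrist/intra-arterial reading pairs; jackknife leave-one-out
    affine calibration of device output to reference pressure; Bland-Altman
    agreement analysis reporting both signed and absolute mean differences
    with limits of agreement and an a-priori validity rule; and
    guideline-threshold hypertension classification with treatment-gap
    quantification and one-tailed Fisher exact sensitivity comparison.
    An end-to-end pipeline ties the stages together with delimited-text
    input/output and a structured run configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
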