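Package: pelvirad
Title: Radiographic Classification of Hemipelvic Displacement Patterns
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Semi-automated measurement of unilateral pelvic ring fracture
    deformity from landmark annotations on standardized anteroposterior,
    inlet, and outlet pelvic radiographs. Mirrors the intact hemipelvis
    across the midsagittal reference to obtain the expected undisplaced
    position of the injured side, measures per-view translational and
    rotational offsets, and classifies the injury into the six basic
    displacement patterns (three translations, three rotations), each
    reported with its anatomical direction. Includes a synthetic projection
    simulator (bilaterally symmetric 3D landmark template, 6-DOF rigid
    displacement of one hemipelvis, orthographic projection, observer
    jitter) providing ground truth for parameter-recovery testing, plus
    Cohen's kappa reliability and validity machinery with Landis-Koch
    interpretation and an in-silico multi-observer study, so every
    component is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
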