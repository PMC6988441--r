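Package: equisight
Title: Horse-Vision Contrast Modelling and Jump Kinematics for Racecourse Obstacles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Models the visibility of racecourse fence components to the
    dichromatic visual system of the horse. Provides visual-pigment
    sensitivity templates, cone-catch integration with von Kries
    adaptation, camera linearization and reflectance equalization against
    in-frame PTFE standards, polynomial camera-to-cone-catch mapping,
    receptor-noise-limited colour and luminance discrimination (JNDs) with
    contrast banding, a synthetic racecourse scene generator with a full
    spectral ground-truth layer covering eight light and weather classes,
    and geometric recovery of eleven jump-kinematics parameters from
    annotated video still frames.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
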