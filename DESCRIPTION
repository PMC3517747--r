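Package: kneekin
Title: Tibiofemoral and Patellofemoral 3D Kinematics from Segmented Knee Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measures three-dimensional knee-joint kinematics from segmented
    magnetic-resonance image volumes or triangulated bone surfaces. Builds a
    tibia-based anatomical coordinate system from the tibial-plateau
    area-centroid, fits a cylinder to the posterior femoral condyles to obtain
    the epicondylar axis and its medial, lateral and central reference points,
    and derives tibiofemoral anterior-posterior translation and axial rotation
    together with four patellofemoral parameters (patellar height,
    patellofemoral angle, patellar tilt and patellar shift) from a
    patella-based coordinate system and trochlear-groove landmarks. A
    parametric synthetic knee generator produces cohorts of healthy and
    PCL-deficient geometries with known ground-truth kinematics so that every
    measurement stage can be validated end to end, and a small statistics
    layer reproduces descriptive summary tables and paired/unpaired
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
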