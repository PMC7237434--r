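Package: hyolingual
Title: Marker-Based Hyolingual Kinematics and Regional Tongue Volumetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for marker-based videoradiographic studies of
    swallowing. Computes rigid-body bone kinematics (jaw pitch, hyoid
    excursion) from implanted marker clusters, extrinsic tongue muscle lengths
    and sagittal orientations, regional tongue volumes from sparse implanted
    markers via spline-bounded harmonic (minimal) surfaces and geometric
    primitives, oral-cavity volume via 3D alpha shapes over posed bony landmark
    clouds, EMG envelope conditioning with a runs-test noise threshold,
    swallow event detection (tongue base retraction onset/offset, intercuspal
    phase), and the per-cycle statistics used to compare kinematic variables.
    Includes a seeded synthetic swallow generator with known ground truth so
    every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    signal,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    picante
Config/testthat/edition: 3
RoxygenNote: 7.3.3
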