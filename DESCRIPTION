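Package: stentsim
Title: Patient-Specific Simulation of Coronary Bifurcation Stenting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A desk-scale, fully testable pipeline for patient-specific
    coronary bifurcation stenting: synthetic bifurcation anatomies and
    OCT-like pullbacks, biplane/OCT fusion 3D reconstruction with
    outer-border completion rules, an OCT-based plaque scoring system
    mapped to reduced-polynomial hyperelastic material models, parametric
    stent and balloon devices with crimping and centerline bending, a
    slice-wise quasi-static deployment surrogate replaying multi-step
    procedures (stenting, POT, side-branch opening, kissing balloon
    inflation), 3D stent reconstruction from strut detections,
    reduced-order non-Newtonian hemodynamics (Carreau viscosity,
    Huo-Kassab flow split, time-averaged wall shear stress), and a
    Bland-Altman agreement harness for lumen and stent diameter profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
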