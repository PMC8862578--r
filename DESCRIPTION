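Package: pediplan
Title: CT-Value-Based Pedicle Screw Trajectory Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic pedicle screw trajectory planning on CT volumes by
    maximizing the mean Hounsfield value of a fixed-size cylindrical screw
    corridor under anatomical safety constraints (full containment in bone,
    passage through the narrowest pedicle section, no breach of the anterior
    vertebral cortex), together with the conventional manual-planning
    baseline, axial/sagittal trajectory position measurements, a T-prime
    Hounsfield-based osteoporosis score, and a parametric synthetic vertebra
    phantom with a linear decalcification model for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
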