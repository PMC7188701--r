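Package: dynfet
Title: Quantification and Prognostic Analysis of Dynamic Amino-Acid Brain PET
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end analysis of dynamic O-(2-[18F]-fluoroethyl)-L-tyrosine
    (FET) brain PET studies in neuro-oncology. Computes static uptake
    parameters (maximum and mean tumour-to-brain ratio, metabolic tumour
    volume by threshold auto-contouring) from a summed 20-40 min image, and
    dynamic parameters (time-to-peak and late-phase slope) from
    time-activity curves extracted with a 2 mL spherical volume of interest.
    Derives prognostic thresholds by ROC analysis with the
    sensitivity-specificity-product optimality rule, and runs univariate
    Kaplan-Meier/log-rank and multivariate Cox proportional-hazards survival
    analyses of the imaging biomarkers. Includes a digital-phantom and
    survival-cohort simulator with recorded ground truth so every stage is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    survival,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
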