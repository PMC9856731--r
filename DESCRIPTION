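Package: tmsmap
Title: TMS Motor Mapping with Volume-Conductor Electric-Field Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyses transcranial magnetic stimulation (TMS)
    motor mapping experiments end-to-end. Generates parameterized synthetic
    layered head models with a central-sulcus-like cortical fold, models a
    figure-8 coil by thin-wire Biot-Savart integration, solves the
    magneto-quasi-static scalar-potential problem on the voxel conductivity
    grid to obtain the induced cortical electric field (EF) for each coil
    placement, localizes muscle representations by multiplying the EF maps
    of the highest motor-evoked-potential (MEP) stimuli, and characterizes
    the EF-MEP dose-response with a sigmoid recruitment model including
    tangent-line EF threshold and saturation estimates. Includes protocol
    generators (sulcus-aligned placement grids), MEP simulation from
    ground-truth sigmoids, hotspot area/center-of-gravity analyses, and
    random-sampling localization-error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
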