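Package: microvent
Title: Ventilation Mapping and Functional Classification for Paired-Phase
    Micro-CT of the Mouse Lung
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for deriving regional ventilation and functional tissue
    classification from paired inspiratory/expiratory micro-CT volumes of the
    mouse lung. Implements grey-level to Hounsfield-unit calibration,
    Laplacian-preconditioned multiresolution Demons deformable registration
    with landmark-based target registration error evaluation, specific gas
    volume (SVg) and ventilation (dSVg) mapping, percentile-threshold
    classification into fibrosis / low-ventilation / normal-ventilation
    compartments, regional density and ventilation biomarkers, histology
    area-fraction morphometry, and a synthetic paired-phase lung phantom with
    known deformation, class map and landmarks for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
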