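Package: avfwss
Title: Pulsatile Hemodynamics and Low Wall Shear Stress Mapping in an
    Idealized Arteriovenous Fistula
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parametric end-to-side radiocephalic arteriovenous fistula
    (AVF) lumen geometry, a finite-volume incompressible Navier-Stokes
    solver on tagged voxel meshes (pulsatile laminar flow, explicit
    projection stepping, sub-voxel ghost-cell wall treatment), wall shear
    stress (WSS) post-processing with thresholded-area metrics and
    cross-section probes, and a blood-redistribution parameter sweep
    quantifying how the proximal/distal radial-artery flow split
    (including retrograde distal flow) changes the low-WSS area at the
    anastomosis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
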