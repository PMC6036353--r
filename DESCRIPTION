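Package: fajtrace
Title: Flat-Absorbing Jaw-Tracking Collimator Model for VMAT/IMRT Monte
    Carlo Dose Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A fast secondary-collimator model for linac Monte Carlo dose
    calculation. Phase-space particles are recycled with azimuthal
    redistribution and ray-traced through perfectly absorbing jaw planes
    placed at the top surface of each collimator pair, with jaw motion
    synchronized to dynamic MLC apertures by fractional monitor-unit
    sampling. Includes IAEA-dialect phase-space I/O, a synthetic photon
    source, a treatment-plan model with VMAT sub-field and IMRT parallel
    splitting, a kerma ray-trace voxel dose engine, absolute dose
    conversion with monitor-backscatter weighting, and a 3D gamma/chi/RMSD
    dose-comparison stack.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
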