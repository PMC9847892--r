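Package: thoraxmc
Title: Voxelized Monte Carlo Photon Migration in Thoracic Tissue for
    Near-Infrared Pulmonary Embolism Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo simulation of near-infrared photon packets in
    labeled voxel volumes emulating the human thorax. Provides a synthetic
    thoracic phantom generator (skin/fat/bone/muscle/lung layers with a
    pulmonary-artery cylinder and embedded blood vessels), a compiled
    photon-transport kernel (Henyey-Greenstein scattering, Fresnel
    boundaries, Russian roulette), spatial sensitivity distributions via
    the three-point Green's-function product of forward and adjoint
    fluence, differential and partial pathlength factors over
    source-detector separation sweeps, and an orchestrated
    pulmonary-embolism severity study linking blood oxygen saturation to
    detected light intensity through a linear fit.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
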