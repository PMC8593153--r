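Package: rhizoCT
Title: Root-Soil Micro-CT Image Analysis: Segmentation, Root Architecture
    and Soil Kinematics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for time-series 3D X-ray computed tomography of
    plant roots growing in granular soil. Provides pre-processing (histogram
    peak matching, contrast stretching, downscaling, bilateral denoising),
    four-phase segmentation (air, water, sand, root) including a 3D
    variance-filter root segmentation and marker-based watershed grain
    labelling, root-system architecture extraction from 3D skeletons
    (branch hierarchy, lengths, cross-section sizes, root length density),
    rhizosphere porosity profiles in coaxial shells around root axes,
    degree-of-saturation maps, and soil kinematics via local digital image
    correlation and discrete particle tracking with volumetric and
    deviatoric strain invariants. A synthetic scene generator produces
    CT-like root-in-sand volumes with full ground truth (phases, skeleton,
    grain centres, analytic displacement fields) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    igraph,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
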