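Package: tumor3d
Title: Histology-Based 3D Reconstruction and Invasion-Front Morphometry of Tumor Serial Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs three-dimensional tumor architecture from serial
    double-immunostained histological section images and quantifies the
    invasion front. Provides a synthetic phantom generator for the four
    canonical oral squamous cell carcinoma invasion architectures rendered as
    DAB/Vector-SG brightfield sections; rigid (translation + rotation) stack
    registration; Beer-Lambert colour deconvolution of cytokeratin (DAB) and
    Ki67 (SG) chromogens; anisotropic voxel-volume assembly with the
    two-consecutive-slice nucleus noise filter; detection of discohesive
    cancer foci by 3D connected components with boundary exclusion and
    dilation-based detachment validation; and case-level morphometry (tumor
    parenchyma volume, parenchymal-stromal border area, S/Vp, Ki67 density,
    focus size distributions) with report writers. A reference 14-case
    morphometry series is bundled for consistency checks of derived
    quantities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
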