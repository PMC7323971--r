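Package: vasc3d
Title: 3D Reconstruction of Mucosal Microvasculature from Serial
    Immunostained Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs three-dimensional colonic-mucosa microstructure from
    ordered serial immunostained sections (vessel-wall stain with unstained
    lumens, periodic epithelium stain) and quantifies which microvessels are
    visible on magnifying blue-laser endoscopy as a function of depth below
    the mucosal surface.  Provides a synthetic tissue-phantom generator with
    exact ground truth, stain-positive segmentation with vessel-lumen filling
    and broken-wall rescue, rigid slice-to-slice registration, anisotropic
    volume stacking with mucosal-surface extraction and per-vessel depth
    measurement, depth-windowed top-view projections, a virtual narrow-band
    endoscopy renderer, and a nonparametric visible-versus-invisible depth
    comparison (exact and tie-corrected Mann-Whitney U) with a
    visibility-boundary estimate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
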