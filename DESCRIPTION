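Package: octcortex
Title: Label-Free OCT Cortical Neuroimaging: Cell-Body Segmentation,
    Morphometry and Longitudinal Elastic Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis stack for label-free optical coherence tomography
    (OCT) volumes of the mouse cortex. Cell bodies, which appear as
    circular dark foci in en-face slices, are segmented by circular-kernel
    convolution with a per-slice percentile threshold followed by 3D
    morphological acceptance rules; myelinated axons (bright filaments)
    are segmented with four oriented line kernels. Downstream tools
    compute depth-blocked morphometry (density, mean cell volume, mean
    nearest-neighbor distance), longitudinal rigid and block-wise elastic
    iterative-closest-point registration of cell centroids with quadratic
    smoothing, cell matching, and cortical elasticity maps. A synthetic
    phantom generator with known ground truth (spherical dark cells,
    tubular vessels, bright filaments, multiplicative gamma speckle,
    analytic inter-session deformations) makes the whole pipeline
    testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
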