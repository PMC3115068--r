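Package: pmdti
Title: Diffusion Tensor Analysis Pipeline for Post-Mortem Whole-Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for diffusion-weighted MRI of whole,
    fixed, post-mortem human brains acquired on clinical scanners. Provides a
    synthetic digital-specimen generator emulating fixed-tissue diffusion
    properties (low diffusivity, radial cortical anisotropy, a low-FA band at
    the gray-white border, zero-signal background), simulation of B0-drift and
    eddy-current image distortions, their correction by constrained and full
    12-degree-of-freedom mutual-information registration, voxelwise diffusion
    tensor fitting with scalar map derivation, regression of region-of-interest
    diffusion indices onto post-mortem and scan intervals, partial-volume
    resolution simulation, inclusion-mask streamline tractography, and
    segmented-EPI acquisition timing arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
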