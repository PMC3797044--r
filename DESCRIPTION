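Package: tractnet
Title: Diffusion MRI Phantom Cohorts, Deterministic Tractography and
    Network Connectivity Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of diffusion-weighted MRI at the
    study scale of a small two-group animal cohort. Generates multi-tensor
    phantom brains with known fiber bundles, region atlases and coupled
    behavioral outcomes; fits the diffusion tensor and derives fractional
    anisotropy and Westin shape coefficients; reconstructs analytic Q-ball
    orientation distribution functions and runs deterministic streamline
    tractography; extracts region-logic fiber networks (required AND /
    at-least-one-of OR traversal rules) with fiber-count-ratio and mean-FA
    metrics; performs voxel-based group comparison and rank-correlation
    mapping with affine registration, tensor reorientation and
    edge-preserving smoothing; and scores open-field and object-recognition
    behavioral assays with the associated group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    pracma,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
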