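Package: nvcoupling
Title: Neurovascular Coupling Analysis of Homotopic Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes voxel-mirrored homotopic connectivity (VMHC) from
    resting-state 4D volumes, standardized cerebral blood flow (CBF) maps
    from arterial-spin-labeling difference images, their voxel-wise ratio
    and gray-matter-wide spatial coupling, followed by lesion-aware
    voxel-wise group statistics with Benjamini-Hochberg false-discovery-rate
    control and covariate-controlled brain-behavior partial correlations.
    Includes a synthetic two-group cohort generator (stroke patients with
    left-hemisphere lesions versus controls) with planted homotopic
    correlations, CBF-VMHC spatial coupling and region-behavior effects, so
    that every pipeline stage can be validated against known ground truth
    without access to patient MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
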