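Package: fdelast
Title: Finite-Deformation Elastography by Inverse Finite-Element Topology Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs spatial maps of relative stiffness in stiff soft
    tissues and biomaterials from imaged finite-deformation displacement
    fields. Displacement-encoded MRI phase maps are converted to
    displacements, unwrapped and smoothed (robust LOWESS or mask-normalized
    Gaussian), meshed into 2D/3D finite-element models, and inverted by
    density-based topology optimization: per-element relative densities scale
    a baseline Young's modulus (SIMP with unit exponent) and are iteratively
    updated with adjoint sensitivities and cone filtering to minimize the
    maximum weighted displacement mismatch at internal nodes under measured
    Dirichlet boundary data. Includes parametric phantom generators (bilayer,
    stiff/soft inclusions, stiffness gradients, 3D two-layer cylinders),
    Monte-Carlo bias/precision analysis, and Cotter two-level factor
    sensitivity ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
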