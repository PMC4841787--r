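Package: ventricle3d
Title: Symmetric Template Shape Analysis of the Brain's Third Ventricle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Model-based three-dimensional shape analysis of the brain's
    third ventricle from binary segmentation masks. Builds a mirror-symmetric
    template surface with an explicit midplane, fits it to individual masks by
    three-degree-of-freedom rigid initialization followed by progressive
    Laplacian surface deformation with midplane constraints (handling the
    inter-thalamic adhesion as a contact of the lateral walls), and derives
    vertex-wise deformity maps, midsagittal width and asymmetry measures,
    mesh-mask similarity metrics, and vertex-wise robust regression against
    clinical covariates. Includes a synthetic phantom generator for
    validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    MASS,
    RANN,
    RNifti,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
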