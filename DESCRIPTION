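Package: nucmorph3d
Title: 3D Morphometry of Cell Nuclei and Nucleoli from Binary Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Robust genus-zero surface reconstruction from 3D binary
    segmentation masks via iterative Laplace-Beltrami eigen-projection with
    topology-preserving mask deformation, extraction of six geometric
    morphometry measures (volume, surface area, mean curvature, shape
    index, curvedness, box-counting fractal dimension), aggregation of
    nucleolar features into fixed-length nucleus signature vectors, and
    cell-set classification under Leave-2-Opposite-Groups-Out
    cross-validation, with a synthetic voxel-phantom generator for
    validation against analytic geometry.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    tiff,
    pracma,
    ranger,
    xgboost,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
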