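Package: gnaam
Title: Gauss-Newton Fitting of Active Appearance Models and Part-Based
    Deformable Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Training and Gauss-Newton inverse-compositional fitting of
    statistical shape-and-appearance models for landmark localization in
    images. Provides point-distribution shape models (Procrustes alignment,
    PCA, similarity augmentation), piecewise-affine and translational motion
    models, holistic and part-based appearance models with optional dense
    gradient-orientation descriptors, and the full family of project-out and
    simultaneous fitting algorithms (POIC, SIC, Fast-SIC, aFast-SIC,
    E-POIC-v1/v2 and combined E-POIC), including weighted sparse-grid
    variants. A synthetic-data generator with brute-force reference solvers
    supports verification and benchmarking without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
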