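Package: morphface
Title: Clinical 3D Morphable Models of Face Shape
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds statistical shape models (3D morphable models) from
    collections of triangulated facial surface meshes: generalised Procrustes
    alignment, dense correspondence by non-rigid iterative closest point
    template registration, and principal component shape spaces with
    compactness, generalisation and specificity validation. Includes two
    clinical applications for orthognathic (jaw) surgery: linear support
    vector machine diagnosis of patient versus non-patient face shape, and
    regularised-regression simulation of the postoperative face shape from a
    preoperative scan. A synthetic face-cohort generator with known ground
    truth supports end-to-end testing without access to any face database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    e1071,
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
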