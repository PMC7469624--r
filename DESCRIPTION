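Package: moldkit
Title: Patient-Specific 3D-Printable Tumor Sectioning Molds from MRI Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts presurgical MRI segmentations of renal tumors into
    patient-specific, 3D-printable sectioning molds whose knife slots are
    registered to imaging slice locations. Computes a landmark-driven
    sectioning frame (longitudinal or transverse to the kidney long axis),
    anchors the specimen with carved base holes at the hilum and tumor
    contact point, builds a watertight mold mesh by Gaussian smoothing,
    iso-surfacing, decimation and Taubin smoothing, and validates the
    design with Dice overlap and mold quality checks. Also clusters
    co-registered multiparametric MRI maps into tumor habitats by k-means
    and provides a synthetic kidney/tumor phantom generator so the whole
    pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    Matrix,
    Rcpp,
    cluster,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    EBImage,
    optparse
Config/testthat/edition: 3
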