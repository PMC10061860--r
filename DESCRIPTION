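Package: cottontraits
Title: Architectural Trait Extraction from Labeled Cotton Plant Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for single-plant 3D point clouds of defoliated cotton:
    reading and writing labeled clouds (PLY and plain-text tables),
    preprocessing (statistical outlier removal, unit-sphere normalization,
    random down-sampling), slice-wise correction of main-stem/branch label
    confusion after semantic segmentation, extraction of seven architectural
    traits (main stem height and diameter, branch and node counts, branch
    inclination angles and diameters, boll count), per-class segmentation
    metrics, and a procedural generator of labeled cotton-plant point clouds
    with known ground-truth traits for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
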