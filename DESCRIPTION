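Package: habitatlab
Title: Repeatability of Voxel-Wise Radiomics Feature Maps and Robustness of Imaging Habitats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to assess the test-retest repeatability and parameter
    reproducibility of voxel-wise (3D) gray-level co-occurrence matrix
    texture feature maps from CT lesions, and the downstream robustness of
    imaging habitats. Provides seeded synthetic test-retest lung-lesion
    phantoms with known ground-truth subregions, isotropic resampling and
    lesion cropping, image perturbation surrogates (noise addition,
    sub-voxel translation, axial rotation), a voxel-wise GLCM feature-map
    extractor (23 features), agreement metrics (concordance correlation,
    Pearson correlation, 3D structural similarity, gamma-index maps and
    passing rates, Dice overlap), feature ranking by repeatability
    thresholds, and imaging-habitat computation via PCA and K-means with
    Dice-based robustness scoring. Volumes are read and written as NRRD.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    tibble,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
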