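Package: fracmorph
Title: Multi-Aspect Fractal Dimension and Texture Analysis of Brain Tumor Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Box-counting fractal dimension analysis of binary segmentation
    masks of brain tumors and surrounding tissue, computed on three
    morphological aspects of each region (general structure, boundary,
    skeleton), together with gray-level co-occurrence matrix (GLCM) texture
    features, normality-gated two-group statistics with false discovery rate
    correction, and cross-validated support vector machine classification of
    low-grade versus high-grade glioma-like cohorts. Includes a synthetic
    data module that generates reference fractals with analytic dimensions
    and two-group tumor-like cohorts (smooth, well-circumscribed masks
    versus irregular, branched masks with textured interiors) so that the
    whole pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    png,
    e1071,
    EBImage,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
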