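Package: radstab
Title: Reproducibility of Handcrafted Radiomic Features Across In-Plane
    Resolutions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A framework for quantifying how in-plane spatial resolution,
    the choice of interpolation method and target resolution, and ComBat
    empirical-Bayes harmonization affect the reproducibility of handcrafted
    radiomic features extracted from CT images. Provides a digital
    multi-layer texture phantom and a virtual scanner model, in-plane
    resampling with nearest-neighbour, linear, B-spline, Gaussian and five
    windowed-sinc kernels, from-scratch extraction of 91 intensity and
    texture features (GLCM, GLRLM, GLSZM, GLDM, NGTDM) with fixed-bin-width
    discretization, parametric ComBat batch harmonization, and concordance
    analysis based on Lin's concordance correlation coefficient with
    all-pairs intersection and Spearman de-duplication.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
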