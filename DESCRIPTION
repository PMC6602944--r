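Package: radstab
Title: Test-Retest Repeatability of Radiomics Features on Multiparametric MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for assessing the test-retest repeatability of
    radiomics features extracted from volumetric MR images. Provides
    synthetic test-retest phantom cohorts with a known between-/within-subject
    variance structure, whole-image and reference-region intensity
    normalization, an image filter bank (Laplacian-of-Gaussian, undecimated
    wavelet sub-bands, single-voxel intensity transforms), fixed-bin-width
    grey-level discretization, first-order, shape and texture (GLCM, GLRLM,
    GLSZM) feature extraction in 2D and 3D, one-way random-effects ICC(1,1)
    repeatability estimation with F-based confidence intervals, and study-level
    summaries (volume-reference comparison, bin-width sensitivity, rank
    histograms, per-class top features, filter frequency, normalization
    deltas).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
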