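Package: heteromap
Title: Mapping Highly Cellular Tumor Subregions from T2-Weighted MRI
    Radiomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An automated classification pipeline for intratumoral
    heterogeneity mapping in pelvic MRI. Aligns diffusion-weighted and ADC
    volumes to the T2-weighted reference (mutual-information affine plus
    Demons deformable registration), detects the tumor by K-means
    clustering of the high-b-value DWI volume, derives a per-voxel
    cellularity reference from an apparent diffusion coefficient cut-off,
    extracts per-pixel radiomic features (filter bank plus first-order and
    GLCM/GLRLM/GLSZM/GLDM/NGTDM texture statistics) from the T2 region of
    interest, selects features by recursive feature elimination with
    grouped cross-validation, and classifies tumor pixels block-wise with
    linear SVM or SGD models, evaluated leave-one-patient-out. Includes a
    synthetic phantom generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    e1071,
    jsonlite,
    png,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
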