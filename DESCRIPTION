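Package: dceseg
Title: Lesion Segmentation Benchmarking for Dynamic Contrast-Enhanced Breast MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates dynamic contrast-enhanced (DCE) breast MRI lesion
    phantoms with mass and nonmass enhancement morphology and kinetic curve
    classes, segments lesions by fuzzy c-means clustering of voxelwise
    enhancement kinetics and by 2D ("quasi-3D") and 3D U-Net convolutional
    networks implemented in base R, and evaluates segmentation agreement with
    Dice and Hausdorff metrics under stratified by-lesion cross-validation,
    including paired and unpaired nonparametric comparisons of segmentation
    arms with Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
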