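Package: dualPET
Title: Dual-Modality PET Quantification, Radiomics and Paired Comparison
    for Breast Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative comparison of dedicated-breast PET (dbPET) and
    whole-body PET (wbPET) images of the same breast tumor. Provides a
    digital activity phantom and acquisition simulator (Gaussian point
    spread, voxelization, heteroscedastic noise), PERCIST-style uptake
    quantification (SUV/SUL conversion, threshold segmentation, SUL_peak,
    metabolic tumor volume, total lesion glycolysis, tumor-background
    ratios), twenty IBSI-style morphology/intensity/GLCM/NGTDM radiomic
    features computed from first principles, and paired nonparametric
    inference (exact Wilcoxon signed-rank, Hodges-Lehmann median
    differences with confidence intervals, size-stratified fold changes).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
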