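Package: petscoresim
Title: Simulation of Attenuation-Correction Error Propagation into an
    Automated Alzheimer's-Disease PET Score
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how MR-based attenuation-correction (MRAC)
    error in brain FDG-PET propagates into an automated Alzheimer's-disease
    discrimination statistic (a PALZ-style PET score). Provides synthetic
    3D brain-PET phantoms with a voxelwise age effect and regional
    hypometabolism, smooth skull-weighted multiplicative error fields in
    two configurable regimes, the full scoring pipeline (Gaussian
    smoothing, intensity normalization against a preserved-uptake mask,
    voxelwise age regression against a normal database, per-voxel
    t-statistics, AD t-sum and PET score), voxelwise error-map construction
    and injection, and diagnostic-accuracy evaluation (paired tests,
    regression and Bland-Altman agreement, fixed-cutoff classification
    with Wilson intervals, ROC/AUC with Youden-index cutoffs and bootstrap
    confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
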