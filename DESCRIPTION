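Package: petctseg
Title: Modality-Robust PET/CT Tumor Segmentation with Channel Dropout
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multimodal head-and-neck tumor segmentation from paired
    CT and FDG-PET volumes. Implements a 3D encoder-decoder segmentation
    network (conventional and dilated convolution variants) trained with
    input-channel dropout so that a single model remains usable when either
    modality is missing at deployment, together with the surrounding
    pipeline: CT/PET fusion preprocessing (Hounsfield clipping,
    z-normalization, isotropic resampling, field-of-view overlap cropping),
    patch extraction with foreground oversampling and stochastic
    augmentation, deep-supervision Dice plus cross-entropy training,
    sliding-window inference with left-right flip averaging, probability-map
    ensembling, and segmentation evaluation (Dice coefficient, Hausdorff
    distance, volume intraclass correlation with bootstrap dispersion, and
    two-sample z comparisons). A synthetic PET/CT phantom generator provides
    reproducible paired volumes with ground-truth masks so the full pipeline
    can be exercised end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
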