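Package: akstage
Title: Multimodal Staging of Actinic Keratosis from High-Frequency
    Ultrasound and Dermatoscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for three-class staging of actinic keratosis (AK) from
    paired 20 MHz high-frequency ultrasound (HFUS) B-scans and
    dermatoscopic photographs. Provides seeded phantom generators for both
    modalities, a compact contextual-feature-pyramid encoder-decoder for
    skin-layer segmentation (entry echo and subepidermal low echogenic
    band, SLEB), handcrafted HFUS descriptors (morphology, echogenicity
    band ratios, histogram, co-occurrence, local binary pattern and
    scattering-wavelet texture), dermatoscopic preprocessing (frame and
    background removal, dual-polarity hair and ruler removal with
    inpainting) and feature extraction, an SVM staging classifier with
    minimum-redundancy maximum-relevance feature ranking, SMOTE
    oversampling and patient-grouped leave-one-out validation, and
    rank-based group statistics (Kruskal-Wallis, eta squared, Dunn's post
    hoc test with Bonferroni correction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
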