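Package: pwaveiso
Title: P-Wave Isolation from 12-Lead ECGs and Atrial-Fibrillation Risk Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Isolates the P wave from 12-lead sinus-rhythm electrocardiograms
    using masking-signal empirical mode decomposition with a minimum-arclength
    criterion on spike extrema (MA-UPEMD), and derives atrial-fibrillation
    screening features from the isolated P wave: morphology measurements,
    P-loop principal-component projection, grid-based loop descriptors,
    inter-lead dispersion angles and band-power ratios. Includes a synthetic
    12-lead ECG generator with closed-form P-wave ground truth, a Butterworth
    band-pass comparison extractor, wavelet baseline removal, rule-based
    delineation, and a machine-learning stage (SVM, perceptron, random forest,
    gradient boosting) with Youden-index thresholding and sampling-based
    Shapley feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    MASS,
    ggplot2,
    signal,
    e1071,
    randomForest,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
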