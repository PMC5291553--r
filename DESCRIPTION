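Package: ivimr
Title: Intravoxel Incoherent Motion Analysis of Diffusion-Weighted MRI for
    Treatment-Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the biexponential intravoxel incoherent motion (IVIM) model
    to multi-b-value diffusion-weighted MRI using a segmented two-stage
    procedure (log-linear high-b fit for the true diffusion coefficient,
    then constrained Levenberg-Marquardt estimation of the perfusion
    fraction and pseudo-diffusion coefficient), voxel-wise over parameter
    maps or on single signal decays. Includes digital-phantom simulation
    with Rician magnitude noise and NEX averaging, ROI summaries
    (mean parameters, maximum transverse diameter, lesion volume),
    longitudinal delta-parameters, a two-group synthetic cohort generator,
    and the statistics used to evaluate imaging biomarkers of
    neoadjuvant-chemotherapy response: normality-routed group comparisons,
    ROC curves with Hanley-McNeil confidence intervals, Youden-optimal
    cutoffs, exact Clopper-Pearson diagnostic intervals, AUC comparison
    tests, and Spearman correlations with mass shrinkage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    minpack.lm,
    nortest,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
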