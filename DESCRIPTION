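Package: centerflow
Title: Centerline-Based Deep-Learning Surrogate for Aortic Valve Hemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale surrogate modelling of peak-systolic pressure and
    wall-shear-stress in the aorta and aortic valve of aortic-stenosis
    patients. Generates synthetic parametric aorta+valve geometries, solves a
    reduced-order quasi-1D hemodynamics model along the vessel centerline,
    builds a compact centerline-based representation (cross-section averaged
    pressure, segment-averaged wall-shear-stress, rasterized cross-section
    shapes), and trains a shape autoencoder plus a bi-directional LSTM
    sequence model that predicts both quantities from geometry and flow rate.
    Includes the full evaluation layer: RMSE/NRMSE metrics, transvalvular
    pressure-gradient equivalence testing (TOST with Wilcoxon signed-rank
    tests), cohort statistics and perturbation-based explainability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
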