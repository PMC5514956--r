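Package: texstrat
Title: CT Texture Analysis for Treatment Stratification in Hepatocellular
    Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Texture-based stratification of hepatocellular carcinoma patients
    between transarterial chemoembolization (TACE) alone and TACE plus
    sorafenib. Implements band-pass pre-filtration (Laplacian of Gaussian) of
    tumor region-of-interest CT images, Gabor filter-bank and orthonormal Haar
    wavelet texture features, Cox proportional-hazards feature screening with
    forward likelihood-ratio model building, ROC/Youden cut-point
    dichotomization, and Kaplan-Meier subgroup comparison, together with a
    synthetic-data generator (stationary Gaussian random-field textures and
    two-arm exponential survival cohorts) that makes the whole pipeline
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    car,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
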