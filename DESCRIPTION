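Package: mlmsplit
Title: Random-Mutation Kennard-Stone Data Splitting for Spectral
    Classification
Version: 0.1.0
Authors@R:
    person("Spectral", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Train/test data splitting for classification of vibrational
    spectra (infrared, Raman, SERS). Implements the Morais-Lima-Martin (MLM)
    algorithm, a Kennard-Stone max-min sample selection followed by a
    random-mutation exchange of a fixed fraction of train/test pairs,
    alongside random-selection (RS) and classic Kennard-Stone (KS) baselines.
    Ships the full evaluation stack needed to compare splitters: a PCA-LDA
    classifier using a pooled-covariance Mahalanobis discriminant, venetian-
    blinds cross-validation for choosing the number of principal components,
    accuracy/sensitivity/specificity figures of merit, standard spectral
    preprocessing (region excision, Savitzky-Golay smoothing, rubberband and
    asymmetric-least-squares baseline correction, peak and vector
    normalization), and a Monte-Carlo simulation benchmark over a two-class
    multiplicative-normal generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
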