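Package: etongue
Title: Voltammetric Electronic-Tongue Calibration with Wavelet Compression
    and Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and chemometric calibration toolkit for voltammetric
    electronic tongues applied to ternary benzodiazepine mixtures (diazepam,
    flunitrazepam, lorazepam). Provides a phenomenological six-sensor cyclic
    voltammogram simulator, tilted full-factorial calibration designs with a
    random external test set, periodized Daubechies discrete wavelet transform
    compression of the 4512-point raw fingerprint to 144 approximation
    coefficients, a from-scratch single-hidden-layer perceptron regressor with
    the classical MATLAB-style transfer functions and an exhaustive
    architecture search, PCA complementarity diagnostics for the sensor array,
    and NRMSE/regression-line evaluation of obtained-versus-expected
    concentrations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
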