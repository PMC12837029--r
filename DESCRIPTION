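Package: speccal
Title: Sampling Designs and Multivariate Calibration for Overlapping UV-Vis Spectra
Version: 0.1.0
Authors@R:
    person("Analytical", "Toolkit", email = "speccal@example.org", role = c("aut", "cre"))
Description: Toolkit for building and validating multivariate calibration models
    for two-component UV-Vis mixture analysis. Generates calibration and
    validation mixture designs (full factorial, Monte Carlo, Latin hypercube,
    Sobol sequence) and quantifies their space-filling quality; simulates
    strongly overlapping two-component absorption spectra under Beer-Lambert
    additivity with configurable noise; fits partial least squares (NIPALS,
    leave-one-out latent-variable selection) and single-hidden-layer neural
    networks trained by Levenberg-Marquardt with early stopping; performs
    genetic-algorithm wavelength selection with cross-validated RMSE or
    information-complexity (ICOMP) fitness; and runs a full validation battery
    (error metrics, nested cross-validation with bootstrap intervals,
    Y-randomization, applicability domain, pooled t and variance-ratio F
    comparison statistics, Friedman test) plus a solvent greenness index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
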