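Package: nirfruit
Title: Non-Destructive Fruit Composition Prediction from Vis/NIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for estimating total soluble solids (TSS)
    and the BrimA taste index of fruit from visible/near-infrared reflectance
    spectra. Provides spectral I/O and preprocessing (absorbance transform,
    scatter correction, wavelet denoising), simulated-annealing selection of
    key wavelengths scored by a multilayer-perceptron objective, an
    imperialist-competitive-algorithm tuner of network structure, NIPALS
    partial least squares regression as the linear comparator, a
    repeated-random-split evaluation harness, and a synthetic spectra
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
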