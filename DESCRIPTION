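Package: spindist
Title: Interspin Distance Distributions and Spin-Label Mobility from CW-EPR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of continuous-wave electron paramagnetic resonance (CW-EPR)
    spectra of site-directed spin-labeled proteins. Implements the dipolar
    convolution forward model (nitroxide powder spectrum broadened by a Pake
    kernel averaged over Gaussian interspin distance distributions), a bounded
    one- or two-Gaussian fitting engine with multistart Levenberg-Marquardt and
    Monte-Carlo/simplex optimizers and chi-squared model comparison, spin
    quantification by double integration, the Goldman effective rotational
    correlation time, two-component spectral subtraction, and a synthetic
    spectrum generator for rigid-limit and motionally averaged nitroxide
    lineshapes.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    lhs,
    pracma,
    yaml,
    withr,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
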