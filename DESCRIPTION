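Package: volecall
Title: Synthesis and Multivariate Analysis of Vole Distress Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the inheritance of distress-call acoustics in
    voles and their interspecific hybrids. Provides a synthetic call generator
    that emulates the published per-species parameter distributions (harmonic
    stacks with arch-shaped frequency modulation plus band-limited noise),
    spectrogram-based extraction of the standard bioacoustic parameters
    (duration, peak frequency, energy quartiles, spectral entropy, fundamental
    frequency and its modulation range, harmonic/noise/mixed structure), and
    the multivariate inference chain used to place hybrids relative to the
    parent species: two-group linear discriminant analysis with split-half
    cross-validation and a label-permutation chance level, chi-squared
    comparison of attribution rates, and squared Mahalanobis distances of
    individuals from the parental centroids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    tools,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
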