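Package: fluorosteps
Title: Single-Molecule TIRF Analysis: Photobleaching Step Counting,
    Colocalization and Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated toolkit for single-molecule total internal
    reflection fluorescence (TIRF) microscopy. Simulates photobleaching
    intensity traces and EMCCD-like single-molecule movies with full ground
    truth; enhances image stacks and detects fluorescent foci with sub-pixel
    Gaussian fitting; maps spots between colour channels with automatic
    chromatic-aberration correction; counts photobleaching steps with a
    compact convolutional-recurrent neural network trained on the simulator
    and locates step positions with a convolutional network; links
    single-particle tracks, fits mean square displacement curves with an
    adaptive range, and deconvolves diffusivity mixtures with a Gaussian
    mixture model; and infers complex stoichiometries from step-count
    histograms under a binomial labelling model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    minpack.lm,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
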