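Package: wavesynth
Title: Signal-Adapted Wavelet Synthesis and Continuous Wavelet Transform
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesizes mother wavelets adapted to a user-selected signal
    fragment (for example an ocular artifact in an electroencephalogram) by
    fitting polynomial, cubic-spline, radial-basis-function network, or
    multilayer-perceptron models to the tapered fragment, then enforcing the
    zero-integral and unit-energy admissibility conditions by iterative offset
    correction and normalization. Provides the forward continuous wavelet
    transform with the synthesized (or reference Mexican hat / Haar) wavelets,
    scalogram export, peak localization at a target scale, and the inverse
    transform via the admissibility constant. Includes seeded generators for
    EEG-like test signals with embedded artifacts, CSV signal input/output,
    JSON model serialization, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    ggplot2,
    jsonlite,
    pracma,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
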