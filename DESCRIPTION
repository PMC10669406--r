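Package: aimorse
Title: Adaptive Fuzzy Timing Recognition for Image-Based Morse Code Input
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decodes Morse code typed through facial movements for
    augmentative and alternative communication (AAC). Mouth open/close
    durations, derived from 68-point facial landmark streams, are
    classified into dots, dashes and short/long silences by a fuzzy
    time-recognition controller that adapts its duration threshold
    on-line via clamped prediction error, five-set fuzzy inference and
    center-of-gravity defuzzification. Includes the supporting image
    conditioning operators (logarithmic and gamma illumination
    compensation, confidence-driven automatic straightening), a
    synthetic typist simulator with ground-truth labels for end-to-end
    evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    png
Config/testthat/edition: 3
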