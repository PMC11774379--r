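Package: wavescrub
Title: Online Wavelet-Based Adaptive Artefact Denoising for Single-Channel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Online, fully automated identification and mitigation of transient
    artefacts in single-channel EEG streams. Consecutive fixed-length windows
    are decomposed with a multi-level discrete wavelet transform, arranged into
    a level-normalised scaleogram, and screened column-by-column with an
    extended isolation forest trained on a sliding buffer of recent windows.
    Flagged coefficient columns are attenuated towards the buffer medoid and
    the window is reconstructed with the inverse transform. Ships an
    instantiation for eye-blink removal, a synthetic blink-EEG generator with
    ground truth, VEOG-style peak-detection ground-truthing, and evaluation
    utilities (oracle signal-to-noise ratio, Jensen-Shannon divergence,
    window-level confusion metrics). Reads and writes delimited text and
    EDF/BDF recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    tools,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
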