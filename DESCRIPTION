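Package: pgesr
Title: Automated Detection of the End of Postictal Generalized EEG Suppression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the end of postictal generalized EEG suppression (PGES),
    i.e. the onset of the first intermittent slow wave (ISW), from 8-channel
    postictal scalp EEG. Implements band-pass preprocessing into 1-second
    epochs, a 612-dimensional feature set (time-domain and Hjorth parameters,
    low-frequency band powers, three-level Daubechies-4 wavelet statistics,
    interchannel correlations), a bagged random-forest segment classifier,
    confidence-based temporal correction rules, and time-distance evaluation
    metrics (predicted time distance, tolerance-based positive prediction
    rate) with a recording-level repeated 10-fold cross-validation harness.
    Includes a synthetic postictal EEG generator with graded artifact
    contamination and a minimal EDF reader/writer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
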