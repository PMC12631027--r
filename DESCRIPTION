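Package: eagwave
Title: Odor Classification from Electroantennogram Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for classifying odors from insect electroantennogram
    (EAG) local field potentials. Provides a synthetic EAG session generator
    with calibration deliveries, per-antenna gain variability and
    responsiveness decay; min-max calibration normalization against a
    reference odor; power-spectral-density quality control; genetic-algorithm
    tuning of Butterworth band-pass filter parameters by Fisher class
    separability in principal-component space; PCA waveform features with
    confidence ellipses of class means; support-vector-machine and
    random-forest classifiers evaluated with antenna-grouped repeated splits
    and balanced accuracy; and an exact binomial McNemar test for paired
    classifier comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    signal,
    e1071,
    randomForest,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
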