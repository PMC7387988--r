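Package: sfcnn
Title: Spatial-Frequency CNN Decoding of Motor-Imagery EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes binary motor-imagery states from multichannel EEG by
    transforming raw trials into spatial-frequency energy maps (an overlapping
    Butterworth filterbank followed by log-variance band power and per-cell
    z-score normalization) and classifying the maps with small convolutional
    neural networks whose first layer learns spatial filters over electrodes.
    Includes full-batch training with Adam or Adadelta, fixed-split and
    10-fold cross-validation protocols, learned-spatial-filter extraction,
    and a synthetic event-related-desynchronization EEG simulator so the
    entire pipeline can be exercised without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
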