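Package: eegtrio
Title: EEG Emotion Recognition with a Tri-Classifier Ensemble Tuned by
    Shark-Smell-Updated Bald Eagle Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for valence/arousal emotion recognition from multichannel
    EEG. Provides band-pass preprocessing and epoch segmentation, a
    four-family feature extractor (discrete wavelet transform sub-band
    statistics, clinical band powers, spectral flatness, and a
    Bernoulli-map-weighted "improved" entropy), a tri-classifier ensemble
    (LSTM, RNN, and a contrastive-divergence pretrained deep belief network)
    whose readout weights are tuned by a hybrid shark-smell-updated bald
    eagle search (SSU-BES) metaheuristic, an eleven-metric evaluation and
    ablation protocol, and a synthetic trial-structured EEG generator so the
    whole pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
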