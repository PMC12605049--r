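Package: cprsca
Title: Channel-Partitioned Multi-Scale Spatial-Channel Attention Networks for EEG Seizure Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the CPRSCA attention mechanism (channel-partitioned
    multi-resolution feature extraction with depthwise separable convolutions,
    coordinate attention, and squeeze-and-excitation) and a CPRSCA-ResNet
    classifier for window-level epileptic seizure detection from multichannel
    EEG. Includes EDF reading and writing with seizure interval annotations,
    the standard preprocessing chain (channel selection, bipolar montage,
    anti-aliased resampling to 256 Hz, 3-second windowing, ictal/interictal
    labeling), a synthetic spike-and-wave EEG generator for fully reproducible
    experiments, and patient-dependent and leave-one-subject-out evaluation
    protocols with confusion-matrix metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
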