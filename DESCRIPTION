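Package: emgadapt
Title: Cross-User Surface-EMG Gesture Recognition with Adaptive Domain-Adversarial Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying the cross-user problem in myoelectric
    (surface-EMG) gesture recognition. Provides a multi-subject synthetic
    EMG generator with controllable inter-subject and inter-repetition
    variability, digital preprocessing (60 Hz notch, 20 Hz high-pass,
    overlapped 151/50 ms windowing), five handcrafted feature sets (TD,
    TDAR, TDPSD, LSF4, LSF9), a linear discriminant analysis classifier,
    canonical-correlation-analysis (CCA) cross-user adaptation by
    regularized least squares, a per-channel temporal convolutional
    network, and an adaptive domain-adversarial network (ADANN) with
    per-subject batch-normalization statistics and a two-neuron domain
    head that adapts to an unseen user from a single repetition of each
    gesture. Includes within-subject, single-repetition and
    leave-one-subject-out evaluation frameworks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    ggplot2,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
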