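Package: ambiguitynet
Title: Multimodal Analysis of Emotion-Ambiguity Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested analysis pipeline for studying how the brain processes
    ambiguous facial emotion, spanning four recording modalities. Provides
    logistic psychometric fitting (threshold and sensitivity of fear
    judgments over morphed faces), single-neuron ambiguity-coding selection
    and differential response latency with cluster/FDR thresholding and
    permutation inference, event-related EEG cross-channel coherence seeded
    at Pz, delta-band amplitude-amplitude cross-frequency coupling,
    directed-transfer-function connectivity on multivariate autoregressive
    models of source time series, and a linear model predicting
    amygdala-dmPFC functional connectivity from behavioral ambiguity
    sensitivity. A synthetic-data module generates behavioral sessions,
    Poisson spike trains, oscillatory EEG epochs with controlled coherence
    and coupling, and MVAR source series with known ground truth, so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
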