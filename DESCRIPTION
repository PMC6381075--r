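Package: wmosc
Title: Oscillatory EEG Analysis of Visual Working-Memory Errors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for analysing EEG oscillatory correlates of
    visual working-memory performance: BrainVision input, Butterworth
    filtering, epoching, FastICA ocular-artifact removal, sliding Hanning
    spectrograms with percent-change baseline normalisation, equal-N trial
    balancing with response-time prioritisation, individual central frequency
    (ICF) detection and alignment, nonparametric cluster-based permutation
    contrasts over channel-frequency-time triplets, and the accompanying
    behavioural statistics (Friedman, Wilcoxon signed-rank with effect sizes,
    Spearman correlations, serial-position accuracy). Includes a synthetic
    cohort generator producing continuous EEG with condition-dependent theta
    and alpha-beta bursts plus matched behavioural tables, so the full
    analysis is testable without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    nortest,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
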