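Package: vulneeg
Title: Simulated EEG Cohorts and Biomarker Pipelines for Depression-Vulnerability Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether resting-state and task-based EEG can
    distinguish groups with high versus low vulnerability to depression.
    Generates synthetic two-group multichannel EEG cohorts with planted
    band-limited amplitude and phase-lagged coupling effects over a 1/f
    background, together with sustained-attention (SART) event sequences and
    questionnaire tables. Provides deterministic preprocessing (zero-phase
    band-pass filtering, epoching, baseline correction, peak-to-peak artifact
    rejection, neighbor interpolation, average re-referencing), extraction of
    depression biomarkers (band powers, relative gamma, frontal alpha
    asymmetry, correlation, coherence, phase-locking value, phase-lag index,
    Higuchi fractal dimension, detrended fluctuation analysis), channel-wise
    group statistics with Benjamini-Hochberg false-discovery-rate correction
    and topographic masking, binary wrapper feature-subset selection by grey
    wolf, genetic and particle-swarm optimization over decision-tree fitness,
    and desk-scale classifier benchmarking (decision tree, multilayer
    perceptron, 1-D convolutional, LSTM and bidirectional LSTM networks) with
    sample-level and subject-level validation splits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    rpart,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
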