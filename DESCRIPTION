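Package: ripplesift
Title: Detection and Classification of Hippocampal High-Frequency
    Oscillations and Their Impact on Place Coding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing high-frequency oscillations (HFOs) in
    hippocampal CA1 local field potentials from chronically epileptic and
    control animals. Detects candidate events by equiripple band-pass
    filtering (140-800 Hz) and sliding RMS thresholding, classifies them
    into ripple-like and pathological HFO (pHFO) populations by k-means on
    slow-envelope amplitude and peak oscillation frequency with ROC
    discrimination against a control-ripple reference, quantifies theta
    power and running-speed dynamics around events with Morlet wavelets and
    a causal/zero-phase filter phase-extrapolation procedure, tests
    single-unit firing-rate modulation with signed-rank statistics, and
    computes place-coding metrics (Skaggs spatial information, split-half
    stability, sparsity) together with shuffle nulls and targeted spike
    down-sampling to measure the immediate impact of pHFOs on spatial
    information. Includes a synthetic-session generator (LFP, spikes,
    trajectory, epochs) with ground-truth labels so the whole pipeline is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
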