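Package: pursuitmon
Title: Continuous Pursuit-Tracking Behavior and EEG Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for continuous action monitoring experiments
    based on pursuit tracking. Generates sum-of-sinusoid target trajectories
    and counterbalanced session plans, simulates cursor behavior and
    multichannel EEG with known ground truth, and implements the analysis
    chain: tracking-error and pursuit-latency metrics with prominence-based
    peak matching, sample-entropy interval analysis, vincentile binning with
    bootstrap paired tests and false-discovery-rate control, Morlet
    time-frequency band power with cluster-based permutation statistics,
    source-contrast ratio maps with density-based voxel clustering, and
    direction-change-locked ERP analysis including a current-source-density
    transform and an ERP-by-performance vincentile matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
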