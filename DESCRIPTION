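Package: corticosleep
Title: Offline Corticostriatal Sleep Analyses for Rodent Skill Learning
Version: 0.1.0
Authors@R: person("Sleep", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multiday motor-cortex (M1) and dorsolateral
    striatum (DLS) recordings around skilled reach training. Provides rodent
    NREM/REM/wake staging from LFP delta power and theta ratio, detection of
    NREM rhythms (sleep spindles, slow oscillations, delta waves),
    multitaper M1-DLS LFP coherence with online/offline decomposition,
    spike-phase locking via circular statistics, interval-jitter
    cross-correlogram inference of short-latency M1-to-DLS spike coupling,
    PCA-based cross-area trajectory prediction, and reach-kinematics learning
    metrics. A synthetic session generator plants ground truth (sleep
    architecture, rhythms, coupled spike trains, coherence drift, reach
    convergence) so every stage is verifiable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
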