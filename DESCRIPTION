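Package: ictal2p
Title: Seizure-Related Event Detection for Two-Photon Calcium Imaging with
    Simultaneous EEG
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated detection of seizure-related events in paired
    two-photon calcium imaging and single-channel EEG recordings from
    chemoconvulsant seizure models. Implements trace normalization with
    neuropil correction, zero-phase Butterworth low-pass filtering, a
    slope-integral feature for calcium event detection, EEG spike-wave
    discharge detection with spectral-ratio exclusion and matched-kernel
    recovery, seed-guided per-cell recruitment detection for pre-ictal
    spikes, seizure wavefront invasion and terminal spreading waves,
    evaluation metrics against manual labels (tolerance matching,
    accuracy, F1, Poisson chance baseline, pre-ictal SNR), L1-regularized
    spatial plane regression for traveling-wave velocity and direction
    with a spatial-shuffle significance test, and a synthetic paired
    recording generator with exported ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    optparse,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
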