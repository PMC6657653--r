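Package: megreplay
Title: Decoding and Sequenceness Analysis of Fast Neural Replay in MEG-Like Data
Version: 0.1.0
Authors@R:
    person("Replay", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify fast sequential reactivation ("replay") of
    decoded neural states in resting multichannel recordings. Provides a
    synthetic MEG generator with known ground truth (evoked state patterns,
    injected replay sequences, an alpha-band nuisance oscillation), sparse
    logistic decoders of state reactivation, a time-lagged regression measure
    of sequenceness against hypothesized transition matrices with
    permutation-based max-statistic thresholds, detection of individual
    replay onsets, event-locked time-frequency contrasts with cluster-based
    permutation statistics, and a seeded end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
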