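Package: burstconn
Title: Transient Burst Detection and Burst-Coincidence Connectomics for
    Regional Electrophysiological Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transient high-amplitude ("burst") events in regional
    electrophysiological recordings (MEG/EEG virtual-sensor time courses)
    using univariate hidden Markov models on time-delay-embedded data, and
    characterises inter-regional coordination through burst-coincidence
    (Jaccard) connectomics.  Includes signal conditioning (zero-phase
    band-pass filtering, multivariate symmetric orthogonalisation for
    source-leakage correction, anti-aliased resampling, standardisation),
    beta-band Morlet amplitude envelopes, resting-state burst summary
    metrics, trial-locked burst-probability and coincidence dynamics around
    motor events, a non-parametric group-statistics battery
    (Wilcoxon rank-sum, Benjamini-Hochberg, Spearman), recursive
    random-forest feature selection with cross-validated SVM classification
    of connectomes, and a synthetic-data generator that plants known burst
    and coordination structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    data.table,
    jsonlite,
    ranger,
    e1071,
    pROC,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
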