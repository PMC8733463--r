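Package: ictalprint
Title: Multimodal Ictal Fingerprints from Subcutaneous EEG, Estimated EMG
    and Trunk Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds person-specific "ictal fingerprints" from annotated
    multimodal recordings: two-channel bipolar subcutaneous EEG (207 Hz),
    a surface-EMG estimate derived from the EEG frequency content above
    20 Hz, and three-axis trunk accelerometry (10 or 20 Hz). Provides EDF
    signal input/output with per-signal sampling rates, a deterministic
    synthetic cohort generator with planted per-person ictal signatures,
    cohort filtering and ictal/pre-ictal/baseline segmentation, a
    catalogue of roughly seventy spectral, EMG and movement features,
    Random-Forest Gini-importance feature selection under 5-fold
    cross-validated grid search, and a fitted fingerprint model
    (Z-scoring, principal components, per-person seizure centroids) with
    nearest-centroid clustering accuracy, radar-chart summaries and
    ictal versus pre-ictal/baseline separation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    pracma,
    randomForest,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
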