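Package: ecglvh
Title: Voltage Criteria for Left Ventricular Hypertrophy Detection from
    12-Lead Electrocardiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated electrocardiographic detection of left ventricular
    hypertrophy (LVH). Implements the adjacent-precordial-overlap
    (Witteles-Somani) voltage criterion alongside the Sokolow-Lyon, Cornell,
    and Peguero-Lo Presti criteria, computed per heartbeat and aggregated to
    one value per ECG as the maximum over lead combinations of the median
    across beats (MMCV). Includes a Christov adaptive-threshold QRS detector,
    R/S-wave amplitude delineation against a PR-segment baseline,
    echocardiographic reference labels via the Devereaux left-ventricular mass
    formula indexed to body surface area, evaluation statistics (confusion
    metrics, McNemar agreement, ROC/AUROC, Pearson correlation with LV mass
    index), and a synthetic 12-lead ECG generator with controllable per-lead
    amplitudes and a planted mass-voltage relationship for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
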