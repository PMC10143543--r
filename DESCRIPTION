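Package: dualgait
Title: Dual-System Gait Analysis from Instrumented Insoles and Ankle IMUs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts gait events and spatiotemporal gait features independently
    from plantar-pressure insole recordings (threshold-based heel/toe contact
    state machine) and from ankle-worn gyroscope recordings (thresholded peak
    detection of toe-off, mid-swing and initial-contact events), quantifies the
    agreement between the two sensing systems (Pearson correlation, intraclass
    correlation for single fixed raters, Bland-Altman limits of agreement), and
    classifies Parkinsonian gait impairment from the extracted features with
    four standard machine-learning models. A synthetic gait-signal generator
    renders both modalities from one shared ground-truth event timeline so the
    whole pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    signal,
    pracma,
    stats,
    e1071,
    randomForest,
    xgboost,
    rpart,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
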