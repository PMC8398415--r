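Package: feedscan
Title: Behaviour Classification and Feeding-Event Detection from
    Collar Accelerometer and GPS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for remote behaviour classification of collared
    carnivores from single-axis accelerometer bursts, and for detection
    of feeding events by fusing the classified burst stream with GPS
    location clusters. Implements burst ingestion and polyphase
    resampling, six spectral and moment predictors per burst, a bank of
    six supervised classifiers with probability thresholding and two
    ensemble voters, leave-one-out and per-animal cross-validation, a
    sliding-window feeding-cluster detector matched to GPS clusters with
    boundary correction and pre-event activity scanning, and a synthetic
    collar-data simulator with ground truth so the whole pipeline can be
    exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    e1071,
    randomForest,
    rpart,
    caret,
    geosphere,
    signal,
    tibble,
    dplyr,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
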