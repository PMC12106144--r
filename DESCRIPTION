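Package: adlmonitor
Title: Daily-Activity Behavior Modelling and Anomaly Detection for Smart Homes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts labeled smart-home sensor-event streams into day-by-day
    activity "dedication" profiles (percentage of each calendar day spent in
    each recognized activity of daily living), forecasts each resident's
    next-day profile from a sliding window of previous days with a family of
    recurrent neural predictors, and flags anomalous days with a two-step
    statistical test: a Gaussian z-score on next-day prediction errors gated
    by per-activity boxplot-whisker deviations, so every alert is explained by
    the concrete activities that deviated. Includes a seeded synthetic-routine
    generator with anomaly injection for end-to-end validation, k-means
    discovery of daily-routine archetypes with silhouette scoring, and a thin
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    FNN,
    e1071,
    randomForest,
    nnet,
    rpart,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
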