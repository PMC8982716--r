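Package: glucodrnn
Title: Dilated Recurrent Neural Networks for Blood-Glucose Forecasting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for 30-minute blood-glucose forecasting in
    type-1 diabetes from 5-minute continuous glucose monitor (CGM) data.
    Includes a minimal-model glucose-insulin-meal simulator with clinical-style
    sensor defects, CGM preprocessing (gap detection, linear interpolation,
    median filtering, causal extrapolation), sliding-window construction with
    glucose/insulin/meal/time-of-day channels, a dilated vanilla-RNN forecaster
    trained by backpropagation through time with RMSprop and two-phase transfer
    learning, classical baselines (ARX, feed-forward network, RBF support
    vector regression), and forecast evaluation by RMSE, MARD, cross-correlation
    time lag and paired t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    xml2,
    optparse
Config/testthat/edition: 3
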