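Package: ecgdann
Title: Domain-Adversarial Classification of Printed 12-Lead ECG Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting cardiac conditions directly from images of
    printed 12-lead electrocardiogram (ECG) pages, including pages captured
    with a mobile device camera. Implements a domain-adversarial convolutional
    network (gradient-reversal layer with an adaptive exponential lambda
    schedule, dual checkpoint criterion, alternating source/mixed-batch
    protocol) together with a fully synthetic data path: a parametric 12-lead
    ECG signal generator, a printed-page renderer with configurable vendor
    formats, and a software simulator of mobile-capture artifacts
    (perspective, illumination, occlusion, crumple, blur, noise). Includes
    binary-classification evaluation utilities (sensitivity, specificity,
    predictive values, accuracy, F1, ROC-AUC, Youden threshold selection) and
    a desk-scale source-to-target adaptation benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
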