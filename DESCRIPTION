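Package: fedsepsis
Title: Federated Multi-Modal Early Sepsis Prediction from Sparse Electronic
    Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for early sepsis warning from sparse,
    multi-modal electronic health records. Generates seeded synthetic
    event-stream cohorts with planted ground truth, labels sepsis onset with
    the Sepsis-3 operationalization (suspected infection paired with a SOFA
    rise of at least 2 points from baseline), builds hourly care-episode
    window grids with three missingness strategies (carry-forward plus
    global mean, distinct sentinel value, and generative adversarial
    imputation), pools clinical-note embeddings into per-window text
    features, trains a long short-term memory (LSTM) per-window predictor
    with balanced oversampling and random hyper-parameter search, simulates
    federated training with weighted-average and server-optimizer
    aggregation, and evaluates with AUPRC, AUROC, and prediction earliness
    in hours.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
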