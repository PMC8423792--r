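Package: fedstudy
Title: Federated Replication of Health Studies with Differential Privacy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for replicating epidemiological and clinical
    studies under federated learning. Generates synthetic binary-outcome
    cohorts (tabular, cluster-randomized, and EHR-like token-sequence data)
    with known generating coefficients, partitions them into units of
    federation (per-patient, natural silos, Dirichlet random silos), trains
    regularized generalized linear models and embedding feed-forward networks
    by federated averaging with optional central or local differential
    privacy (Gaussian mechanism with Renyi differential-privacy accounting),
    and computes study endpoints -- odds and risk ratios with Wald confidence
    intervals, cluster-robust standard errors, and AUC under repeated
    train/test splits -- from federated (per-client additive) sufficient
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    pROC,
    withr
Config/testthat/edition: 3
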