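Package: freda
Title: Privacy-Preserving Federated Domain Adaptation for Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a privacy-preserving federated pipeline for
    unsupervised domain adaptation in regression, aimed at small-sample,
    high-dimensional biomedical data such as DNA-methylation age
    prediction. Per-feature Gaussian-process regressors are trained across
    distributed source clients using randomized-encoding masked matrix
    products and zero-sum-mask secure aggregation, so that the target
    client obtains predictive distributions for every feature without any
    party revealing raw data. Predictive confidences are converted into
    per-feature penalty weights for a weighted elastic net trained with
    FedAvg, with the regularization strength selected per target group
    from domain-similarity scores (or by cross-validation). Includes a
    synthetic multi-domain data generator with planted covariate shift, a
    centralized reference path, a protocol transcript with a privacy
    audit, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
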