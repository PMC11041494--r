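Package: fedsurv
Title: Federated Survival Support Vector Machines with Secure Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits linear survival support vector machines (regression
    objective with a squared hinge for right-censored observations) on
    horizontally partitioned data. Clients exchange only aggregate
    statistics (local objective, gradient and Hessian), optionally masked
    by additive secret sharing over a fixed-point ring, while a
    coordinator runs truncated Newton (Newton-CG) optimization; the
    federated fit is mathematically equivalent to centralized training.
    Includes federated z-score normalization, one-hot encoding with a
    federated category union, Harrell's concordance index with a
    mean-of-sites federated variant, closed-form linear SHAP
    attributions, a right-censored synthetic-data generator, and an
    end-to-end cross-validated workflow over per-client CSV files.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
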