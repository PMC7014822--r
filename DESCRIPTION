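Package: tgxpod
Title: Transcriptomic and Apical Points of Departure by Benchmark Dose Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Dose-response inference for toxicogenomic risk assessment.
    Fits PROAST-style exponential and Hill benchmark-dose (BMD) models to
    continuous apical endpoints with a sex-by-time covariate and
    profile-likelihood BMDL/BMDU bounds; per-gene transcriptomic BMD
    modeling (Hill, power, linear, polynomial, exponential families) at a
    benchmark response of 1.349 residual standard deviations with a
    four-rule filter cascade; Fisher-exact gene-set enrichment and a
    battery of pathway-agnostic and pathway-based point-of-departure (POD)
    aggregation strategies; and a DEG-count POD estimator that fits a
    fixed-plateau Hill curve to the number of K-fold differentially
    expressed genes per dose by Poisson-weighted iteratively reweighted
    least squares and bootstraps its one-tailed 95% lower bound (D1*).
    Includes a synthetic dose-response study generator with known ground
    truth for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    methods,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
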