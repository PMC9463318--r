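Package: opsccbn
Title: Bayesian-Network Clinical Decision Models for Oropharyngeal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds, learns and iteratively abstracts discrete Bayesian-network
    clinical decision models for primary treatment selection in oropharyngeal
    squamous cell carcinoma (OPSCC). Provides exact inference by variable
    elimination, maximum-likelihood conditional-probability-table estimation
    with pseudocount smoothing from complete categorical patient records,
    clinically guided model-abstraction operators (state merging, variable
    condensation, transitivity resolution for independence of causal influence,
    leaky noisy-OR compilation, binarization), k-fold cross-validated
    micro-accuracy and ROC/AUC evaluation, a synthetic OPSCC cohort generator,
    and serialization to CSV, JSON, YAML recipes and GeNIe-compatible XDSL.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
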