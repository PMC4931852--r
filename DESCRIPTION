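Package: swabage
Title: Cell Composition-Aware Epigenetic Age Prediction for Buccal Swabs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Epigenetic age prediction from buccal swab DNA methylation that
    accounts for the specimen's variable mixture of buccal epithelial cells
    and leukocytes. Provides frozen implementations of five published
    pyrosequencing-based predictors (a 3-CpG blood model, a retrained 3-CpG
    swab model, a 1-CpG model, a two-CpG Buccal-Cell-Signature estimating the
    percentage of epithelial cells, and a 5-CpG mixture model), together with
    the full training pipeline: ordinary least-squares age models, inverted
    one-CpG regression, cytology-anchored calibration of the cell signature,
    and mixture-weighted estimation of the epithelial age model. A marker
    screen identifies cell-type-specific CpGs between two tissue data sets
    with an age-correlation veto, and a synthetic cohort generator emulates
    the two-cell-type mixture structure so every analysis path can be
    exercised end to end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
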