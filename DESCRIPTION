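Package: cyclesim
Title: Semi-Mechanistic Simulation of Multi-Hormone Menstrual-Cycle Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates physiologically constrained daily trajectories of
    estradiol, estrone, LH, FSH, AMH, testosterone and GnRH daily area for
    virtual eumenorrheic and PCOS-like subjects over multiple menstrual
    cycles, using Gaussian-bump hormone kinetics with stochastic
    between-subject and between-cycle variability. Includes the downstream
    phenotype-discrimination pipeline: per-subject feature aggregation,
    standardization, principal component analysis, k-means clustering and a
    stratified train/test logistic-regression evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
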