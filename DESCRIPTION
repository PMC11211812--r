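Package: codexr
Title: Counterfactual Modeling of High-Throughput Perturbation Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counterfactual deep-learning models for high-throughput
    perturbation screens in cancer cell lines and single cells. A shared
    encoder maps an unperturbed expression profile to a latent state,
    intervention-specific branch networks (optionally conditioned on drug
    dosage) shift that state, active branches are summed, and a shared
    decoder maps the aggregate to either a scalar drug-synergy score or a
    heteroscedastic Gaussian prediction of the perturbed transcriptome.
    Includes gene-set Jaccard proxy vectors for predicting entirely unseen
    perturbations, linear and ablation baselines, leave-combination-out and
    leave-perturbation-out cross-validation, evaluation metrics on top
    differentially expressed genes, and a ground-truth simulator of
    perturbation screens with controllable interaction effects, Hill-curve
    dose responses and pathway structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    fgsea,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
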