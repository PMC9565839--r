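Package: hdlungct
Title: CT-Based Latent-Trait Phenotyping of Humidifier-Disinfectant-Exposed Lungs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end quantitative computed-tomography (CT) pipeline for
    characterizing lungs exposed to aerosolized humidifier disinfectants.
    Paired inspiratory/expiratory lung volumes are combined with the
    registration Jacobian into two-channel images; lobule-sized 3D patches are
    clustered into tissue-pattern classes by a 3D convolutional autoencoder
    with a feature constructor; per-subject pattern-frequency histograms are
    reduced by exploratory factor analysis; subjects are clustered in factor
    space and profiled with parametric-response-map and density metrics,
    heteroscedastic group statistics, a decision-tree classifier, and a 1D
    conducting-airway resistance and aerosol-deposition surrogate. A fully
    synthetic cohort generator with known ground truth (planted tissue
    patterns, analytic deformation Jacobians, binary airway trees) makes every
    stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml,
    rpart
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
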