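Package: agingProfiles
Title: Connectome and Cognition Profiles of Brain Aging via Partial Least
    Squares Regression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Links structural connectivity, functional connectivity and
    cognitive performance to chronological age in older adults. Builds
    significance-thresholded, Fisher-transformed, sign-split functional
    connectomes and log-transformed structural connectomes on a parcellated
    cortex, reduces them to node-wise intra- and inter-network strength
    estimates, composes a PCA-based global cognition score, and extracts
    age-characteristic aging profiles by NIPALS partial least squares
    regression with leave-one-out RMSEP, permutation-based component
    selection, scrambled null models and repeated train/test splits. A
    synthetic-cohort generator with planted latent components makes every
    stage testable without access to cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
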