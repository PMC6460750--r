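Package: orchardgblup
Title: Pedigree and Genomic BLUP for Open-Pollinated Seed-Orchard Trials
Version: 0.1.0
Authors@R:
    person("Orchard", "Genomics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genetic evaluation of open-pollinated forest-tree progeny
    trials with pedigree-based (BLUP) and marker-based (GBLUP) linear
    mixed models. Builds numerator (A) and trace-scaled genomic (G)
    relationship matrices, estimates variance components by
    average-information REML with expectation-maximisation fallback,
    reports narrow-sense heritability and prediction-error-variance
    based breeding-value accuracy, and evaluates models by replicated
    10-fold cross-validation within, between and across seed orchards,
    plus truncation-selection genetic gain. Includes marker quality
    filtering, EM imputation of missing dosages, composite-r2 linkage
    disequilibrium decay curves, spectral decomposition of relationship
    matrices, and a deterministic synthetic-data generator emulating a
    two-orchard open-pollinated breeding trial.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
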