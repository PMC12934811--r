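Package: panscreen
Title: Harmonization and Probabilistic Modeling of Multi-Study Ex Vivo Drug Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating heterogeneous ex vivo and cell-line drug
    viability screens: drug-name harmonization via an alias graph, a
    contrastive Bayesian tensor-factorization dose-response model that
    imputes monotone-down curves with uncertainty, robust empirical-null
    de-batched z-scores, population-level differential-sensitivity
    analyses (tissue-vs-rest, metastatic-vs-primary, cell-line-vs-ex-vivo,
    embedding k-nearest-neighbor analyses), a few-shot transformer for
    in-context dose-response prediction with omics probes, and a
    synthetic multi-study screen generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    pROC,
    nnet,
    ranger,
    xgboost,
    glmnet,
    fgsea
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
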