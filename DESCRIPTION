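Package: ensdm
Title: Ensemble Species Distribution Modeling and Niche Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully scriptable pipeline for ensemble habitat
    suitability modeling and climate-niche dynamics: spatial thinning of
    occurrence records, Pearson-correlation filtering of collinear bioclimatic
    predictors, pseudo-absence sampling, a nine-algorithm model suite (GLM,
    GBM, GAM, CTA, ANN, SRE, FDA, RF, MAXENT-style) with repeated 80/20
    evaluation by ROC-AUC and the true skill statistic (TSS), TSS-gated
    committee-averaging and weighted-mean ensembles on a 0-1000 suitability
    scale, species range-change statistics (loss/stable/gain/absent pixel
    bookkeeping), and PCA-env niche quantification with Schoener's D overlap
    and equivalency/similarity permutation tests. Ships a seedable
    virtual-species generator (spatially autocorrelated, cross-correlated
    climate-like rasters with known true suitability) so every stage is
    testable against ground truth without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    mgcv,
    nnet,
    rpart,
    randomForest,
    xgboost,
    glmnet,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
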