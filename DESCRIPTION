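Package: renalphen
Title: Rule-Based and Model-Based Phenotyping of Chronic Kidney Disease from Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated identification of advanced chronic kidney
    disease (CKD stage III or higher) and of no known kidney disease (NKD)
    from heterogeneous electronic health record components: serum-creatinine
    time series (via CKD-EPI eGFR and KDIGO-style acute kidney injury
    detection on irregular series), ICD-10 billing codes and ICD-10 codes
    pre-extracted from discharge summaries. Includes simple categorical
    classifiers per source and their logistic combinations, a per-patient
    feature builder parameterized by data-availability scenarios, grid-search
    cross-validated training of elastic-net, random-forest and
    single-hidden-layer neural-network models, an evaluation stack (confusion
    metrics, AUROC and AUCPR with confidence intervals, DeLong comparisons),
    and a seeded synthetic-cohort simulator with known ground-truth kidney
    status for end-to-end testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    nnet,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
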