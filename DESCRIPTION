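Package: proteoTriage
Title: Proteomic Therapy Triage for AML from RPPA Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Survival-driven analysis of reverse-phase protein array (RPPA)
    profiles of acute myeloid leukemia to triage patients between
    venetoclax/hypomethylating-agent (VH) therapy and conventional chemotherapy
    (CC). Implements a quantile-sweep prognostic protein screen, progeny
    (stability) clustering, sequential protein-selector construction with
    outcome-based cluster labelling, a three-stage random-forest classifier
    cascade with SHAP-guided protein subset selection, one-vs-rest differential
    expression, protein correlation analysis, and a counterfactual
    triage-benefit projection. Ships a synthetic RPPA cohort generator with
    planted cluster signatures and cluster-by-arm exponential survival so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    cluster,
    randomForest,
    knitr
biocViews: Proteomics, Survival, Clustering, Classification, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
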