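Package: mmpscore
Title: Gene-Set Consensus Subtyping and Prognostic Signature Scoring for
    Tumor Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Resampling-based consensus clustering of a curated gene set
    (matrix metalloproteinase genes in the motivating application) with
    CDF/delta-area selection of the cluster number, one-vs-rest moderated-t
    differential expression between the resulting molecular subtypes,
    construction of prognosis-oriented gene signatures A and B, Boruta
    shadow-feature reduction, a per-sample PC1-difference score with median
    dichotomization, and the downstream survival (Kaplan-Meier, log-rank,
    univariate Cox, time-dependent IPCW AUC), clinicopathological, mutation
    and ridge-based drug-response association analyses. Includes a synthetic
    cohort generator with planted ground truth for end-to-end validation,
    and a configuration-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    ranger,
    limma,
    jsonlite,
    yaml
Suggests:
    cluster,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
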