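Package: mirnadx
Title: Cross-Platform miRNA Expression Profiling and PCA-Based Tumor
    Diagnosis
Version: 0.1.0
Authors@R:
    person("mirnadx", "maintainers", email = "mirnadx@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of small-RNA sequencing miRNA expression
    profiles alongside matched microarray measurements: readers for
    miRDeep2-style count tables and Agilent-style processed-signal exports,
    per-sample z-score normalization, probe-to-miRNA averaging,
    cross-platform and technical-replicate concordance on log expression,
    PCA-based unsupervised outlier feature extraction followed by linear
    discriminant classification with leave-one-out cross-validation
    (accuracy, sensitivity, specificity, AUC, one-sided Fisher exact p),
    exact Wilcoxon rank-sum differential testing, novel-miRNA candidate
    filtering, and a negative-binomial simulator that emulates the
    statistical structure of paired tumor/control hepatic miRNA profiling
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
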