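Package: painscreen
Title: Literature-Driven Pain Gene Discovery and Twin Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for prioritizing candidate pain genes
    from public data. Ranks diseases by a literature-derived disease-specific
    pain index (the fraction of a disease's citations co-annotated with the
    "pain" subject heading), extracts per-disease differential expression with
    the Rank Product statistic and Storey q-values, screens genes whose fold
    changes correlate with the pain index by Spearman rank correlation with a
    permutation-based positive false discovery rate, validates the resulting
    prioritization against a gold-standard gene set by ROC analysis with
    resampling confidence bands, and tests candidate SNPs for association with
    experimental pain phenotypes in a twin cohort using pair-averaged
    observations and heteroscedastic generalized least squares. A synthetic
    data generator emulates every input (citation counts, case/control
    expression studies, and MZ/DZ twin cohorts with planted SNP effects) so
    the full pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    nlme,
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
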