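Package: herbmine
Title: Prescription-Pattern Mining of Chinese Herbal Medicine Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Reconstructs prescription patterns of Chinese herbal medicine
    (CHM) from ambulatory claims data. Provides typed readers and writers
    for a delimited claims format, cohort selection by ICD-9 diagnosis and
    treatment modality, prevalence, dose and dosing-frequency summaries,
    level-wise Apriori frequent-itemset mining with support/confidence
    association rules, and weighted co-prescription networks with
    core-treatment identification.  A synthetic claims generator with
    closed-form ground truth (planted core formulas and conditionally
    co-prescribed adjuvants) supports end-to-end validation, and a pipeline
    runner orchestrates simulate/filter/stats/mine/network stages into a
    reproducible, manifest-tracked run.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
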