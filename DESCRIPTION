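Package: mpnscope
Title: Integrative Pharmacoscopy and Clinical Proteotype Analysis for
    Myeloproliferative Neoplasms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to score ex vivo drug responses of patient blood cells
    from single-cell immunofluorescence features (pharmacoscopy), to process
    DIA proteome intensity matrices (normalization, outlier flagging,
    group-structured missingness filtering, left-censored imputation,
    hemoglobin-contamination regression), to derive minimal discriminative
    protein signatures by repeated cross-validated recursive feature
    elimination, to run preranked gene-set enrichment with a permutation
    null, and to integrate drug responses with proteotypes and clinical
    annotations (drug-proteome correlation, replicative MCM signatures,
    variant-allele-frequency correlates, subgroup drug differentials).
    Ships a seeded synthetic-cohort generator with planted effects so every
    stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    nnet,
    jsonlite,
    stats,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
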