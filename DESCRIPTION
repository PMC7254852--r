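Package: metabOPLS
Title: Chemometric Severity Ranking of Gene Variants from Targeted
    Metabolomics Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Preprocessing and latent-variable modelling for targeted
    metabolomics concentration panels (Biocrates p180-like), aimed at ranking
    missense variants of a gene by the severity of their metabolic signature.
    Implements the full chain used in cell-model severity studies: limit of
    detection filtering, bridge-sample batch normalization, total-sum (row)
    normalization and autoscaling; NIPALS principal component analysis with
    Hotelling T2 outlier limits; single-response orthogonal projections to
    latent structures (OPLS) and its discriminant form (OPLS-DA) with variable
    importance in projection (VIP); cross-validated Q2Y, permutation null
    models and CV-ANOVA significance; and a signature pipeline deriving
    volcano tables, lipid-class indices (PUFA/MUFA sums and ratios,
    sphingomyelin ratios, polyamine ratios) and regressions against the first
    latent score. A synthetic-data generator with planted ground truth
    emulates the two-batch, seven-group study design so every stage is
    testable without access to raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'conditions.R'
    'AllGenerics.R'
    'AllClasses.R'
    'tables_io.R'
    'synthetic_data.R'
    'preprocessing.R'
    'latent_models.R'
    'validation.R'
    'pipeline.R'
    'indices.R'
    'runall.R'
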