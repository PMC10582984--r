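Package: BcellPRS
Title: Pathway-Restricted Polygenic Risk Scores for Systemic Lupus
    Erythematosus
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Construction and analysis of pathway-restricted polygenic
    risk scores (PRSs) for systemic lupus erythematosus (SLE), centred
    on a packaged 20-variant B cell gene weight table. Provides genotype
    quality control (call-rate, Hardy-Weinberg exact test, relatedness by
    identity-by-descent, heterozygosity and inbreeding-based sex checks,
    principal-component outlier detection, linkage-disequilibrium
    pruning), log-odds-weighted allele-count scoring with quartile
    grouping, HLA-DRB1 tag-SNP stratification, duration-adjusted
    logistic and age-adjusted Cox association models, and a calibrated
    synthetic cohort generator so that every pipeline stage can be
    exercised and validated without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SNP, GenomeWideAssociation, StatisticalMethod, QualityControl
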