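Package: prscnv
Title: Polygenic and Rare Copy-Number Variant Risk Across Definitions of
    Internalising Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for comparing how common polygenic risk
    (PRS) and rare psychiatric-risk copy-number variants (P-CNVs) associate
    with alternative case definitions of mood, anxiety and combined
    internalising disorder in a biobank-scale cohort.  Includes a synthetic
    biobank generator (Balding-Nichols genotypes, liability-threshold
    phenotypes with shared genetic liability, multi-source phenotype
    records, CNV call tables), multi-source phenotype harmonisation (GAD-7,
    CIDI-SF, clinical code lists), variant and sample quality control, PRS
    scoring with reference-panel principal-component ancestry adjustment,
    CNV quality-control filters and carrier derivation, logistic
    association models with Nagelkerke pseudo R2 and ROC AUC, tetrachoric
    correlations, and a z-test for comparing effect sizes estimated on
    overlapping case-control samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mvtnorm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
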