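Package: prstailor
Title: Optimizing and Calibrating Polygenic Scores for Target Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pragmatic pipeline for tailoring polygenic risk scores (PRS) to a
    target sub-population using public resources: genotype and sample quality
    control, application of PGS Catalog scoring files with allele harmonization,
    principal-component ancestry adjustment of raw scores, percentile calibration
    against a population reference distribution, best-score selection on a
    train/validation split, decile/quintile risk stratification, interaction and
    subgroup analyses, and genetic-distance ancestry matching in external
    biobanks via the squared Mahalanobis distance with a chi-squared boundary.
    Includes a seeded synthetic-cohort generator (Balding-Nichols population
    structure, additive polygenic liability-threshold disease, clinical
    covariates and medication use) so the full pipeline is testable end to end
    without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    MASS,
    optparse,
    pROC,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
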