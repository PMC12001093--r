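Package: mrmort
Title: One-Sample Mendelian Randomisation of Type 2 Diabetes Liability and
    Cause-Specific Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for one-sample Mendelian randomisation of
    genetically-predicted type 2 diabetes (T2D) liability against cause-specific
    mortality in a prospective cohort, together with a synthetic-cohort generator
    that emulates the statistical structure such studies assume (liability-threshold
    disease model, admixed genotypes, confounded cause-specific mortality,
    diabetes-miscoded death certificates). Includes genetic risk score construction
    with allele harmonisation, age-at-risk stratified proportional-hazards and
    logistic estimation, the ratio-of-coefficients (Wald) estimator with
    odds-scale rescaling, pathway and subgroup analyses, and a two-sample
    sensitivity suite (inverse-variance weighted, MR-Egger, weighted median,
    MR-PRESSO).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
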