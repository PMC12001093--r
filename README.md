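# mrmort

One-sample Mendelian randomisation of type 2 diabetes (T2D) liability
against cause-specific mortality, for prospective cohorts followed through a
death registry — plus a synthetic-cohort generator that emulates the
statistical structure such an analysis assumes, so the whole pipeline is
testable without access to restricted cohort data.

## Who this is for

Epidemiologists and statistical geneticists who want a tested, end-to-end
implementation of the one-sample ratio-of-coefficients ("Wald") MR design
for mortality outcomes: polygenic score construction with allele
harmonisation, diabetes-status classification, death-certificate cause
re-attribution, an eligibility cascade with auditable ledgers, age-at-risk
stratified survival estimation, odds-scale reporting, subgroup/pathway
machinery, and a pleiotropy-robustness suite (IVW, MR-Egger, weighted
median, MR-PRESSO) implemented from their defining formulas.

## The statistic at its core

With a genetic risk score $G = \sum_j w_j d_{ij}$ (per-allele log-odds
weights times effect-allele dosages), two regressions are combined:

* $\hat\beta_{GD}$ — log odds of T2D per score unit (logistic; adjusted for
  age, sex, principal components),
* $\hat\beta_{GY}$ — log cause-specific mortality hazard per score unit
  (Cox, time-since-entry timescale, stratified by 5-year age-at-risk band
  and sex via Lexis expansion, PC-adjusted),

giving the Wald estimator

$$\hat\theta = \frac{\hat\beta_{GY}}{\hat\beta_{GD}},$$

the log mortality rate ratio per 1-unit increase in genetically-predicted
log-odds of T2D. Estimates and SEs are multiplied by $\ln 3 \approx 1.10$
so they refer to a *trebling* of predicted odds (a trebling of odds takes a
genetic risk of 10% to 25%, or 25% to 50%); `rescale_base()` converts
exactly between reporting bases (e.g. a per-trebling rate ratio of 2.29 is
a per-doubling rate ratio of 1.69).

## Worked example

Simulate a cohort of 20,000 with 200 instrument SNPs under the default
study conditions (18% T2D prevalence via a liability threshold, a true
score explaining 6% of liability, admixed genotypes, confounded
cause-specific mortality over ~20 years, noisy external weights), then run
the full analysis:

```r
library(mrmort)
library(dplyr)

cfg <- sim_config(n_individuals = 20000, n_snps = 200, seed = 42)
cohort <- simulate_cohort(cfg)

alleles <- tibble(rsid = cohort$panel$rsid,
                  allele1 = cohort$panel$effect_allele,
                  allele2 = cohort$panel$other_allele)
harm <- harmonize_weights(cohort$weights, alleles)
harm
#> <grs_harmonization> 170 SNPs scored; excluded: unavailable 0, ambiguous 30, mismatch 0

grs <- compute_grs(cohort$genotypes, harm)
dat <- mr_input(cohort$phenotypes, cohort$followup, grs)
gen <- apply_exclusions(dat, "genetic")
gen$ledger
#> <exclusion_ledger> initial 20,000
#>   - aged_75_or_older             0
#>   - likely_t1d                   50
#>   - missing_or_extreme_data      0
#>   - uncertain_cause_of_death     0
#>   - duplicate_record             0
#>   - missing_genetic_data         0
#>   remaining 19,950

res <- run_one_sample_mr(gen$data,
                         causes = c("all_cause", "vascular", "infection",
                                    "renal", "cancer"))
tidy(res)
#> # A tibble: 5 × 9
#>   cause      logrr    se    rr conf.low conf.high  base n_events status
#>   <chr>      <dbl> <dbl> <dbl>    <dbl>     <dbl> <dbl>    <int> <chr>
#> 1 all_cause  0.237 0.119 1.27     1.00       1.60     3     1196 ok
#> 2 vascular   0.343 0.243 1.41     0.875      2.27     3      287 ok
#> 3 infection  0.357 0.276 1.43     0.833      2.45     3      222 ok
#> 4 renal      0.390 0.320 1.48     0.789      2.76     3      165 ok
#> 5 cancer    -0.176 0.289 0.839    0.476      1.48     3      202 ok

tidy(attr(res, "denominator"))
#> # A tibble: 1 × 5
#>   term  estimate std.error statistic  p.value
#> 1 score    0.672    0.0488      13.8 3.81e-43
```

Reading the output: 30 of 200 weight-file SNPs were strand-ambiguous
(palindromic) and dropped at harmonisation; 50 individuals with a
likely-type-1 profile left the genetic analysis population; each row of the
result is the mortality rate ratio (with 95% CI) per trebling in
genetically-predicted odds of T2D for that cause, with the number of deaths
it rests on; the denominator fit shows the instrument strength (z ≈ 14
here). At this deliberately modest sample size the CIs are wide — the
causes with true planted effects (vascular, infection, renal) sit above 1
while cancer (no planted effect) straddles it.

`autoplot(res)` draws the forest plot; `observational_mortality()`,
`subgroup_mr()`, `pathway_mr()` and `mr_sensitivity_suite()` cover the
comparison analyses, and `run_pipeline(cfg)` chains the whole thing with a
reproducibility manifest.

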