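---
title: "Methods: one-sample Mendelian randomisation of T2D liability and cause-specific mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-sample Mendelian randomisation of T2D liability and cause-specific mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Observational studies in populations with very high type 2 diabetes (T2D)
prevalence report large excess mortality among people with diabetes, but the
observational contrast mixes any causal effect of T2D with confounding
(adiposity, lifestyle, unmeasured frailty) and reverse causation. Mendelian
randomisation (MR) replaces the measured disease state with a genetic risk
score (GRS): because alleles are allocated at random at conception, a
polygenic score for T2D liability is independent of the classical confounders,
and its association with mortality isolates the component of risk that flows
through genetically-predicted liability.

`mrmort` implements the full one-sample analysis for a prospective cohort
followed for cause-specific mortality, together with a synthetic-cohort
generator that reproduces the statistical structure the analysis assumes, so
that every stage — scoring, cohort assembly, survival estimation, the ratio
estimator and the pleiotropy-robustness suite — is exercisable and testable
without access to any restricted data.

## The estimator

Three regression contracts feed the causal estimate:

1. **Score-exposure (denominator).** Logistic regression of T2D status at
   recruitment (previously diagnosed *or* undiagnosed by HbA1c $\ge$ 6.5%) on
   the GRS, adjusted for age, sex and the leading genetic principal
   components. The coefficient $\hat\beta_{GD}$ is the change in log-odds of
   T2D per GRS unit.
2. **Score-outcome (numerator).** A Cox proportional-hazards fit of
   cause-specific mortality on the GRS with time since study entry as the
   timescale, stratified by 5-year age-at-risk band and sex (a Lexis
   expansion reconciles the entry-time timescale with attained-age strata)
   and adjusted for the principal components. Deaths from other causes are
   censored (cause-specific hazards). The log hazard ratio is read as an
   average causal log rate ratio even under moderate non-proportionality; a
   Schoenfeld-style diagnostic is attached but never gates the pipeline.
3. **Ratio of coefficients (Wald).**
   $\hat\theta = \hat\beta_{GY} / \hat\beta_{GD}$, the log mortality rate
   ratio per 1-unit increase in genetically-predicted log-odds of T2D, i.e.
   per $e$-fold increase in predicted odds. For display the estimate and its
   SE are multiplied by $\ln 3 \approx 1.10$ so they refer to a *trebling* of
   predicted odds (a trebling of odds moves a genetic risk of 10% to 25%, or
   25% to 50%). `rescale_base()` makes this an exact group action, so a
   per-trebling estimate can be re-expressed per doubling and back without
   loss.

The default ratio SE is the numerator SE scaled by $|\hat\beta_{GD}|$
("simple"), which is appropriate when the instrument is strong; a two-term
delta propagation is available by flag, and a weak-instrument warning is
attached whenever $|\hat\beta_{GD}|/\mathrm{se} < 10$. With the simple
method the MR z-statistic equals the numerator z-statistic exactly, which is
the property its tests pin down.

Subgroup analyses refit the numerator per stratum but keep the *overall*
denominator (stratum-specific denominators would add unnecessary random
error); Cochran's Q on the stratum estimates summarises heterogeneity.
Pathway analyses treat each pathway sub-score as an instrument in its own
right, with its own denominator, and flag small instruments (a liver/lipid
style pathway may legitimately carry only 2 SNPs). The observational
comparison runs the identical survival machinery on measured diabetes status
with the conventional covariate adjustment (district, education, smoking,
alcohol, and quarters of height, weight, waist and hip); the genetic and
observational contrasts are reported on their own scales — per trebling of
predicted odds versus per disease state — and the package never converts
between them, because a binary exposure gives the two estimands different
meanings.

## Score construction and harmonisation

Weights arrive as a PGS-style table of per-allele log odds ratios.
Harmonisation against the genotype's counted allele drops SNPs absent from
the genotype data ("unavailable") and strand-ambiguous palindromic A/T and
C/G pairs ("ambiguous" — dropping rather than frequency-based strand
inference is the conservative default), flips dosages ($d \to 2-d$) where
effect and other allele are swapped, and refuses to score irreconcilable
pairs. Missing dosages are mean-imputed at twice the effect-allele frequency
of the non-missing individuals, which is unbiased under missingness at
random; the exclusion report is a first-class result. Scores are carried
both raw (the MR denominator scale) and per-SD (the display scale for
score-disease odds ratios).

## Cohort assembly

Diabetes classification applies, in order of precedence: likely type 1
(self-reported diagnosis before age 35 plus insulin use), previously
diagnosed (self-report or medication), undiagnosed (HbA1c $\ge$ 6.5%), none.
Records with no self-report and missing HbA1c are flagged for the
missing-data exclusion rather than classified.

Death certificates with diabetes as the raw underlying cause are accepted as
diabetes deaths only when the fourth digit marks an acute crisis (coma or
ketoacidosis); other diabetes-coded deaths are re-attributed to the
highest-priority mappable secondary cause (renal > cardiac > stroke >
infection > any other mappable), never silently, and deaths with no mappable
cause become "uncertain" and are excluded. The ICD-10 prefix-to-group table
follows WHO chapter conventions but ships as an editable default — it is a
stand-in, not a canonical endpoint list, and is labelled as such.

The eligibility cascade applies, in order: age 75+ at recruitment, likely
T1D, missing or extreme covariate data (explicit plausibility windows, e.g.
height 100–220 cm, configurable), uncertain cause of death, duplicate
records; then missing genetic data (genetic population) or prior chronic
disease (observational population). Multiply-eligible individuals count
under the *first* matching reason — the tabulation convention is an
assumption, stated here because cascade listings rarely specify it — and
the ledger identity `initial = remaining + sum(excluded)` is enforced.

## The synthetic cohort generator

The generator is first-class, tested code. It emulates:

* **Genotypes.** Independent SNPs under two-way admixture: each individual
  draws an ancestry fraction from a Beta distribution (default mean 0.67),
  each dosage is two allele draws at the individual-specific mixed
  frequency. A configurable fraction of SNPs (default 15%) is palindromic so
  harmonisation always has work to do. No linkage disequilibrium or
  relatedness is simulated (a relatedness column is emitted but constant).
* **Disease.** A liability threshold: liability = true-weighted score +
  standardised confounder contributions + standard normal noise. True SNP
  effects are scaled *analytically* (using the admixture moments) so the
  true score explains the configured share of liability variance (default
  0.06). The threshold is the empirical sample quantile rather than the
  analytic one, so the realised prevalence (default 18%) is matched under
  any confounder configuration. 72% of cases are flagged previously
  diagnosed; the rest rely on HbA1c detection, drawn from an elevated
  distribution (default mean 7.5%, SD 1.5% — a free choice, since the
  HbA1c distribution of undiagnosed cases is not an observed study
  quantity; about a quarter of undiagnosed cases fall below the diagnostic
  threshold, a deliberate imperfect-detection feature). Non-diabetic HbA1c
  is N(5.5, 0.4); diagnosed-case HbA1c is N(9.1, 2.5).
* **Confounding.** Standardised age, adiposity and smoking act on the
  mortality hazard; adiposity and a latent `conf_u` (unmeasured by
  construction) also raise liability. Everything is independent of genotype,
  so the score is a valid instrument while the observational contrast is
  confounded — the study's central structural claim, and the property the
  recovery tests exploit.
* **Mortality.** Independent exponential cause-specific event times
  (constant hazards; a Weibull shape hook exists) with log-hazard = log
  baseline + T2D x cause-specific log rate ratio + covariate terms; the
  earliest event before administrative censoring wins, so competing risks
  are accounted for by construction. Censoring times spread over a
  6-year recruitment-span window around 20 years. Default baseline rates
  and log rate ratios were calibrated once so that a 35–74 cohort accrues
  roughly 10% deaths over 20 years with a plausible cause mix (vascular,
  infectious, renal, cancer, hepatic, respiratory, acute diabetic, other);
  acute diabetic crises occur essentially only among carriers.
* **Planted pleiotropy.** `pathway_direct_effects` optionally gives one or
  more pathways a direct log-hazard effect per SD of their true sub-score —
  mortality risk that bypasses T2D status entirely. It is off by default
  and exists to probe the heterogeneity diagnostics: a pathway with a
  planted direct effect should, and in the tests does, stand out from its
  exchangeable peers.
* **Certification.** Among deaths of T2D carriers from non-acute causes, a
  configurable share (default 30%) is certified with non-acute diabetes as
  the raw underlying cause and the true cause retained as a secondary code,
  which is exactly the situation the re-attribution rule repairs.
* **External weights.** True effects plus Gaussian noise with SD equal to
  the true-effect SD (ratio 1), so the correlation between the weight file
  and in-cohort per-allele estimates is moderate (~0.5), as typically seen
  when transporting weights across ancestries. This also means the
  *realised* GRS explains materially less liability variance than the true
  score does (roughly half, before the loss from dropped palindromic SNPs)
  — attenuation is a feature of the emulated situation, not a bug; the
  Wald ratio is insensitive to it because numerator and denominator
  attenuate together.

Every stage derives its own RNG stream from the master seed, so identical
configs reproduce identical cohorts bit for bit.

### What the generator does not emulate

Linkage disequilibrium, imputation quality, family structure, age-varying
hazards within a cause (beyond the Weibull hook), secular trends, and
probabilistic death-registry linkage error. Passing tests therefore show the
*estimators* behave as claimed under the stated model; they do not certify
behaviour under LD-induced instrument correlation or registry linkage error.

## Two-sample sensitivity suite

Implemented from their defining formulas over a summary-statistic table
(per-SNP exposure and outcome effects with SEs; the in-cohort per-allele
mortality scan supplies the outcome side, the external weight file the
exposure side — no sample overlap is assumed, and that assumption is
documented rather than enforced):

* **IVW**: weighted regression through the origin, weights
  $1/\mathrm{se}_Y^2$; random-effects (default; the choice is exposed
  because published analyses rarely state it) inflates the SE by
  $\max(1, \sqrt{Q/(n-1)})$.
* **MR-Egger**: the same regression with a free intercept after orienting
  exposure effects positive; the intercept estimates directional pleiotropy,
  with a multiplicative dispersion bounded below by 1.
* **Weighted median**: the inverse-variance weight-interpolated 50th
  percentile of per-SNP Wald ratios, SE by seeded parametric bootstrap
  (default 1000 draws); consistent while valid instruments hold at least
  half the weight, a breakdown property the tests demonstrate on both sides
  of 50%.
* **MR-PRESSO**: observed weighted residual sum of squares around
  leave-one-out IVW fits, compared to a parametric simulated null (default
  1000 draws); Bonferroni-corrected per-SNP outlier tests; outlier-corrected
  IVW; and a distortion test whose null, in this implementation, comes from
  random exclusion sets of the same size as the detected outlier set. Inputs
  are internally oriented so results are invariant, bit for bit, to flipping
  any row's alleles.

## Numerical choices

* Cox fits use Efron tie handling (coarse age data produce ties; Efron
  behaves better there), relative log-likelihood tolerance 1e-9, at most
  100 iterations; "loglik converged before variable" warnings on sparse
  adjustment levels are muffled because they do not affect the exposure
  coefficient, while genuine iteration exhaustion is a hard error.
* Strata with no events are dropped before fitting; logistic separation is
  detected and the estimate withheld; monomorphic SNPs are skipped with a
  reason; a constant exposure is a degenerate-design error, never an NA.
* Quantile bins break ties by stable input order, so bin sizes differ by at
  most one even for constant scores.
* Nagelkerke's pseudo-R² is computed from log-likelihoods as
  $[1-(L_0/L_1)^{2/n}]/[1-L_0^{2/n}]$; a fitted likelihood below the null is
  reported as a numerical error, not clamped.

## Problem sizes used by the test-suite and acceptance runs

Chosen as the package's own simulation design: generator calibration oracles
run at n = 50,000 individuals x 1,000 SNPs; the parameter-recovery study
runs 200 replicates of n = 20,000 x 200 SNPs with a single all-cause
endpoint (baseline rate 5e-3/person-year; true per-T2D log rate ratios 0,
ln 1.5, ln 2), with principal components disabled because the generator
plants no population-structure confounding for them to absorb, and the
proportionality diagnostic off inside the loop. The per-effect generative
truth on the per-trebling scale is obtained by running the identical
pipeline once at n = 400,000: under a liability-threshold model a per-T2D
log rate ratio does not equal the per-unit-log-odds estimand (the binary
exposure maps nonlinearly onto predicted odds), so the large-sample run *is*
the generative mapping. The acceptance script's synthetic pipeline uses
n = 50,000 x 400 SNPs, and its per-allele outcome scan covers 150 SNPs.

## Known limitations

Estimates are interpretable as effects of *genetically-predicted liability*,
not of diabetes status; the package deliberately reports genetic and
observational contrasts on different scales. The ICD-10 group table is a
configurable stand-in for a study-specific appendix. The simple ratio SE
ignores denominator error and numerator-denominator coupling (small for a
strong instrument, and the recovery study measures the net effect on
coverage empirically). MR-PRESSO's distortion-test null is this
implementation's variant. No LD-aware estimators are provided.
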