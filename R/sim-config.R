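#' Simulation configuration for the synthetic cohort generator
#'
#' Bundles every tunable of the synthetic-cohort generator: cohort and panel
#' size, the liability-threshold disease model, admixture structure,
#' confounder effects on liability and mortality, cause-specific hazards, and
#' death-certificate miscoding. Defaults emulate a large urban Mexican cohort:
#' ~18% T2D prevalence, a polygenic score explaining ~6% of disease liability,
#' ~20 years of follow-up, and cause-specific death rates whose mix
#' approximates the relative frequencies of vascular, infectious, renal,
#' neoplastic and other deaths seen in such a population.
#'
#' @param n_individuals Number of individuals to simulate.
#' @param n_snps Number of instrument SNPs.
#' @param maf_range Length-2 numeric in (0, 0.5]: range of ancestral minor
#'   allele frequencies.
#' @param target_prevalence Target T2D prevalence (liability-threshold).
#' @param grs_liability_r2 Share of liability variance explained by the true
#'   SNP effects.
#' @param n_pathways Number of pathophysiological pathway labels to partition
#'   causal SNPs into.
#' @param palindromic_frac Fraction of SNPs given strand-ambiguous (A/T or
#'   C/G) allele pairs.
#' @param missing_rate Per-entry dosage missingness rate.
#' @param ancestry_shape Length-2 Beta shape parameters of the per-individual
#'   admixture fraction (defaults give mean 0.67).
#' @param confounder_effects Named list; each element is `c(liability =, hazard =)`
#'   giving the coefficient of that (standardised) covariate on disease
#'   liability and on log mortality hazard. The `conf_u` entry is a latent
#'   (unmeasured) confounder.
#' @param cause_hazards Named list; each element is `c(rate =, log_rr =)`:
#'   the baseline cause-specific death rate per person-year among unaffected
#'   individuals and the log rate ratio conferred by T2D.
#' @param admin_censor_years Mean administrative censoring time (years).
#' @param recruitment_span_years Spread of censoring times, emulating a
#'   staggered recruitment window with a common end of follow-up.
#' @param diabetes_miscode_frac Fraction of non-acute deaths among T2D carriers
#'   whose raw underlying cause is certified as diabetes (exercising the
#'   downstream re-attribution rule).
#' @param diagnosed_frac Fraction of T2D cases flagged as previously diagnosed.
#' @param t1d_frac Fraction of previously diagnosed cases given a
#'   likely-type-1 profile (diagnosis age < 35 and insulin use).
#' @param hba1c_normal,hba1c_diagnosed,hba1c_undiagnosed Length-2 `c(mean, sd)`
#'   of the HbA1c (%) distributions. The undiagnosed-T2D distribution is a free
#'   choice, not an observed study quantity.
#' @param age_range Recruitment age range (years).
#' @param female_frac Fraction of women.
#' @param weight_noise_ratio SD of the noise added to true SNP effects when
#'   emulating an external GWAS weight file, as a multiple of the SD of the
#'   true effects.
#' @param pathway_direct_effects Optional named list mapping a pathway label
#'   to a log-hazard coefficient applied to that pathway's standardised true
#'   sub-score: a *direct*, non-T2D-mediated mortality effect (horizontal
#'   pleiotropy planted at the pathway level), used to probe heterogeneity
#'   diagnostics. Empty by default.
#' @param weibull_shape Shape of the cause-specific event-time model
#'   (1 = exponential, the default; values != 1 give a Weibull-type hook).
#' @param n_pcs Number of genetic principal components to compute from the
#'   simulated dosage matrix (0 skips the computation).
#' @param seed Integer master seed; every stage derives its own stream from it.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 500, n_snps = 20, seed = 1)
#' cfg$target_prevalence
sim_config <- function(n_individuals,
                       n_snps,
                       maf_range = c(0.05, 0.5),
                       target_prevalence = 0.18,
                       grs_liability_r2 = 0.06,
                       n_pathways = 8,
                       palindromic_frac = 0.15,
                       missing_rate = 0.002,
                       ancestry_shape = c(6.7, 3.3),
                       confounder_effects = default_confounder_effects(),
                       cause_hazards = default_cause_hazards(),
                       admin_censor_years = 20,
                       recruitment_span_years = 6,
                       diabetes_miscode_frac = 0.30,
                       diagnosed_frac = 0.72,
                       t1d_frac = 0.015,
                       hba1c_normal = c(mean = 5.5, sd = 0.4),
                       hba1c_diagnosed = c(mean = 9.1, sd = 2.5),
                       hba1c_undiagnosed = c(mean = 7.5, sd = 1.5),
                       age_range = c(35, 74),
                       female_frac = 0.68,
                       weight_noise_ratio = 1,
                       pathway_direct_effects = list(),
                       weibull_shape = 1,
                       n_pcs = 7,
                       seed = 1L) {
  if (!is_count(n_individuals)) abort("`n_individuals` must be a positive integer.")
  if (!is_count(n_snps)) abort("`n_snps` must be a positive integer (invalid config).")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an increasing pair within (0, 0.5].")
  }
  for (f in c(target_prevalence, grs_liability_r2, palindromic_frac,
              missing_rate, diabetes_miscode_frac, diagnosed_frac, t1d_frac,
              female_frac)) {
    if (!is_fraction(f)) abort("fractions in the config must lie in [0, 1].")
  }
  if (target_prevalence <= 0 || target_prevalence >= 1) {
    abort("`target_prevalence` must lie strictly in (0, 1).")
  }
  if (!is_count(n_pathways)) abort("`n_pathways` must be a positive integer.")
  if (!is.list(confounder_effects) ||
      (length(confounder_effects) > 0 &&
       (is.null(names(confounder_effects)) ||
        !all(vapply(confounder_effects, function(x)
          all(c("liability", "hazard") %in% names(x)), logical(1))))) ) {
    abort("`confounder_effects` must be a named list of c(liability=, hazard=) pairs.")
  }
  if (!is.list(cause_hazards) || length(cause_hazards) == 0 ||
      is.null(names(cause_hazards))) {
    abort("`cause_hazards` must be a non-empty named list.")
  }
  rates <- vapply(cause_hazards, function(x) unname(x[["rate"]]), numeric(1))
  if (any(rates < 0) || any(!is.finite(rates))) {
    abort("cause-specific baseline rates must be finite and non-negative (invalid config).")
  }
  if (admin_censor_years <= 0) abort("`admin_censor_years` must be positive.")
  if (weibull_shape <= 0) abort("`weibull_shape` must be positive.")
  if (age_range[1] >= age_range[2]) abort("`age_range` must be increasing.")
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range),
    target_prevalence = target_prevalence,
    grs_liability_r2 = grs_liability_r2,
    n_pathways = as.integer(n_pathways),
    palindromic_frac = palindromic_frac,
    missing_rate = missing_rate,
    ancestry_shape = as.numeric(ancestry_shape),
    confounder_effects = confounder_effects,
    cause_hazards = cause_hazards,
    admin_censor_years = admin_censor_years,
    recruitment_span_years = recruitment_span_years,
    diabetes_miscode_frac = diabetes_miscode_frac,
    diagnosed_frac = diagnosed_frac,
    t1d_frac = t1d_frac,
    hba1c_normal = hba1c_normal,
    hba1c_diagnosed = hba1c_diagnosed,
    hba1c_undiagnosed = hba1c_undiagnosed,
    age_range = as.numeric(age_range),
    female_frac = female_frac,
    weight_noise_ratio = weight_noise_ratio,
    pathway_direct_effects = pathway_direct_effects,
    weibull_shape = weibull_shape,
    n_pcs = as.integer(n_pcs),
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' Default confounder effects
#'
#' Standardised age, adiposity and smoking act on mortality hazard; adiposity
#' and a latent (unmeasured) confounder `conf_u` also raise disease liability,
#' so the observational T2D-mortality contrast is confounded while the genetic
#' score, independent of all of them, is not.
#'
#' @return Named list of `c(liability =, hazard =)` coefficient pairs.
#' @export
default_confounder_effects <- function() {
  list(
    age     = c(liability = 0.30, hazard = 0.80),
    bmi     = c(liability = 0.40, hazard = 0.20),
    smoking = c(liability = 0.00, hazard = 0.30),
    conf_u  = c(liability = 0.40, hazard = 0.40)
  )
}

#' Default cause-specific hazards
#'
#' Baseline death rates per person-year among individuals without T2D and the
#' per-cause log rate ratio conferred by T2D. The mix is calibrated so that
#' over ~20 years a cohort recruited at ages 35-74 accrues roughly 10% deaths
#' with relative cause frequencies resembling a middle-income urban adult
#' population: vascular, infectious, renal, neoplastic, hepatic, respiratory
#' and acute diabetic deaths, plus ill-defined, other-medical and external
#' causes. Acute diabetic crises occur essentially only among T2D carriers.
#'
#' @return Named list of `c(rate =, log_rr =)` pairs.
#' @export
default_cause_hazards <- function() {
  list(
    cardiac                = c(rate = 5.3e-4, log_rr = log(2)),
    stroke                 = c(rate = 1.6e-4, log_rr = log(2)),
    vascular_other         = c(rate = 5.7e-5, log_rr = log(2)),
    infection              = c(rate = 4.9e-4, log_rr = log(3)),
    renal                  = c(rate = 1.3e-4, log_rr = log(15)),
    cancer                 = c(rate = 5.5e-4, log_rr = 0),
    cirrhosis              = c(rate = 2.3e-4, log_rr = log(1.3)),
    copd                   = c(rate = 8.0e-5, log_rr = 0),
    acute_diabetic_crisis  = c(rate = 8.0e-7, log_rr = 7.3),
    other_medical          = c(rate = 2.3e-4, log_rr = log(1.2)),
    ill_defined            = c(rate = 3.0e-5, log_rr = 0),
    external               = c(rate = 9.0e-5, log_rr = 0)
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  individuals: %d, SNPs: %d, seed: %d\n",
              x$n_individuals, x$n_snps, x$seed))
  cat(sprintf("  target prevalence: %.3f, liability R2: %.3f, pathways: %d\n",
              x$target_prevalence, x$grs_liability_r2, x$n_pathways))
  cat(sprintf("  causes: %s\n", paste(names(x$cause_hazards), collapse = ", ")))
  invisible(x)
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar fields override `sim_config()` defaults; `confounder_effects` and
#' `cause_hazards` may be given as named maps of named values.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading YAML configs requires the 'yaml' package.")
  }
  raw <- yaml::read_yaml(path)
  for (fld in c("confounder_effects", "cause_hazards")) {
    if (!is.null(raw[[fld]])) raw[[fld]] <- lapply(raw[[fld]], unlist)
  }
  do.call(sim_config, raw)
}
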