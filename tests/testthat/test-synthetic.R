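test_that("panel generation is deterministic and honours degenerate scaling", {
  cfg <- sim_config(100, 40, seed = 11)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1, p2)

  cfg0 <- sim_config(100, 40, grs_liability_r2 = 0, seed = 11)
  p0 <- simulate_panel(cfg0)
  expect_identical(p0$beta_true, rep(0, 40))

  # palindromic flags match their allele pairs
  pal <- p1$palindromic
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_identical(unname(comp[p1$effect_allele[pal]]), p1$other_allele[pal])
  expect_false(any(comp[p1$effect_allele[!pal]] == p1$other_allele[!pal]))

  # pathway labels partition the SNPs into at most n_pathways groups
  expect_lte(length(unique(p1$pathway)), cfg$n_pathways)
  expect_false(anyNA(p1$pathway))
})

test_that("liability share, prevalence and confounder independence hold at scale", {
  # one large cohort exercises three Monte-Carlo oracles at once
  cfg <- sim_config(50000, 1000, missing_rate = 0, n_pcs = 0, seed = 42)
  panel <- simulate_panel(cfg)
  geno <- simulate_genotypes(panel, cfg)
  phen <- simulate_phenotypes(geno, panel, cfg)

  # share of liability variance carried by the true-weighted score
  r2_hat <- var(phen$score_true) / var(phen$liability_true)
  expect_lt(abs(r2_hat - cfg$grs_liability_r2), 0.01)

  # realised prevalence matches the liability threshold
  expect_lt(abs(mean(phen$t2d_true) - cfg$target_prevalence), 0.01)

  # covariates are independent of the genetic score by construction
  for (v in c("z_age", "z_bmi", "z_smoking", "z_conf_u", "height_cm")) {
    expect_lt(cor(phen[[v]], phen$score_true)^2, 4 / sqrt(nrow(phen)))
  }

  # empirical per-SNP allele frequencies against the admixture expectation,
  # via conservative exact binomial bounds (mixture variance <= binomial)
  shp <- cfg$ancestry_shape
  mu_a <- shp[1] / sum(shp)
  fbar <- panel$maf_pop2 + mu_a * (panel$maf_pop1 - panel$maf_pop2)
  counts <- colSums(geno$complete)
  n2 <- 2 * nrow(geno$complete)
  lo <- qbinom(5e-7, n2, fbar)
  hi <- qbinom(1 - 5e-7, n2, fbar)
  expect_true(all(counts >= lo & counts <= hi))
})

test_that("genotype generation respects symmetry and degenerate mixing", {
  cfg <- sim_config(4000, 30, maf_range = c(0.5, 0.5), missing_rate = 0,
                    n_pcs = 0, seed = 13)
  g <- simulate_genotypes(simulate_panel(cfg), cfg)
  mc_se <- sqrt(0.5 / (4000 * 30))  # var of a dosage at maf 0.5 is 1/2
  expect_lt(abs(mean(g$complete) - 1), 3 * mc_se * sqrt(30))

  # ancestry fraction ~ 0 for everyone: frequencies follow source population 2
  cfg2 <- sim_config(8000, 25, ancestry_shape = c(0.01, 1000),
                     missing_rate = 0, n_pcs = 0, seed = 14)
  p2 <- simulate_panel(cfg2)
  g2 <- simulate_genotypes(p2, cfg2)
  fhat <- colMeans(g2$complete) / 2
  se <- sqrt(p2$maf_pop2 * (1 - p2$maf_pop2) / (2 * 8000))
  expect_true(all(abs(fhat - p2$maf_pop2) < 5 * se))

  # missingness is injected at the configured rate
  cfg3 <- sim_config(2000, 20, missing_rate = 0.05, n_pcs = 0, seed = 15)
  g3 <- simulate_genotypes(simulate_panel(cfg3), cfg3)
  expect_lt(abs(mean(is.na(g3$dosages)) - 0.05), 0.01)
  expect_false(anyNA(g3$complete))
})

test_that("phenotype generation flags diabetes subtypes coherently", {
  co <- shared_cohort()
  ph <- co$phenotypes
  # previously diagnosed fraction among cases near the configured share
  expect_lt(abs(mean(ph$self_report_diabetes[ph$t2d_true]) -
                  shared_config()$diagnosed_frac), 0.05)
  # undiagnosed cases carry elevated HbA1c on average
  undiag <- ph$t2d_true & !ph$self_report_diabetes
  expect_gt(mean(ph$hba1c[undiag]), mean(ph$hba1c[!ph$t2d_true]) + 1)
  # diagnosis ages exist only for the diagnosed
  expect_true(all(is.na(ph$diag_age[!ph$self_report_diabetes])))
  expect_false(anyNA(ph$diag_age[ph$self_report_diabetes]))
})

test_that("a signal-free instrument yields a null score-disease association", {
  cfg <- sim_config(20000, 50, grs_liability_r2 = 1e-8, missing_rate = 0,
                    n_pcs = 0, seed = 16)
  panel <- simulate_panel(cfg)
  geno <- simulate_genotypes(panel, cfg)
  phen <- simulate_phenotypes(geno, panel, cfg)
  phen$s_std <- as.numeric(scale(phen$score_true))
  fit <- fit_logistic(phen, "t2d_true", "s_std")
  expect_lt(abs(fit$beta), 3 * fit$se)
})

test_that("mortality generation matches its closed-form exponential oracle", {
  # all baseline rates zero: nobody dies
  cfg0 <- sim_config(500, 5, seed = 21, n_pcs = 0,
                     cause_hazards = list(all = c(rate = 0, log_rr = 0)))
  co0 <- simulate_cohort(cfg0)
  expect_equal(sum(co0$followup$died), 0)

  # single cause, no T2D effect, no covariate effects, fixed censoring time
  r <- 0.004; T <- 15
  cfg1 <- sim_config(30000, 5, seed = 22, n_pcs = 0,
                     confounder_effects = list(),
                     cause_hazards = list(all = c(rate = r, log_rr = 0)),
                     admin_censor_years = T, recruitment_span_years = 0)
  co1 <- simulate_cohort(cfg1)
  p_death <- 1 - exp(-r * T)
  ci <- qbinom(c(2.5e-4, 1 - 2.5e-4), 30000, p_death)
  expect_gte(sum(co1$followup$died), ci[1])
  expect_lte(sum(co1$followup$died), ci[2])

  # exactly one exit per individual; cause labels only on deaths
  fu <- co1$followup
  expect_equal(nrow(fu), 30000)
  expect_true(all(fu$exit_age > fu$entry_age))
  expect_true(all(is.na(fu$true_cause_group) == !fu$died))
})

test_that("a planted log-RR of ln 2 is recovered by the crude rate ratio", {
  cfg <- sim_config(40000, 5, seed = 23, n_pcs = 0,
                    confounder_effects = list(),
                    cause_hazards = list(all = c(rate = 0.002, log_rr = log(2))),
                    admin_censor_years = 15, recruitment_span_years = 0)
  co <- simulate_cohort(cfg)
  fu <- co$followup
  d <- co$phenotypes$t2d_true
  py <- fu$exit_age - fu$entry_age
  rr_hat <- (sum(fu$died[d]) / sum(py[d])) /
    (sum(fu$died[!d]) / sum(py[!d]))
  se_log <- sqrt(1 / sum(fu$died[d]) + 1 / sum(fu$died[!d]))
  expect_lt(abs(log(rr_hat) - log(2)), 3.5 * se_log)
})

test_that("death-certificate miscoding is confined to T2D carriers", {
  co <- shared_cohort()
  fu <- co$followup
  ph <- co$phenotypes
  miscoded <- fu$died & fu$cause_icd10 == "E11.9"
  expect_true(all(ph$t2d_true[miscoded]))
  # non-acute miscodes retain the true cause as a secondary code
  non_acute <- miscoded
  expect_true(all(nzchar(fu$secondary_causes[non_acute])))
  # miscoding rate among eligible deaths near the configured fraction
  eligible <- fu$died & ph$t2d_true &
    fu$true_cause_group != "acute_diabetic_crisis"
  if (sum(eligible) > 50) {
    expect_lt(abs(mean(fu$cause_icd10[eligible] == "E11.9") -
                    shared_config()$diabetes_miscode_frac), 0.1)
  }
})

test_that("external weights attenuate towards truth as configured", {
  cfg <- sim_config(100, 1000, seed = 31, n_pcs = 0)
  panel <- simulate_panel(cfg)

  w0 <- simulate_gwas_weights(panel,
                              sim_config(100, 1000, seed = 31, n_pcs = 0,
                                         weight_noise_ratio = 0))
  expect_equal(w0$weight, panel$beta_true)

  w_big <- simulate_gwas_weights(panel,
                                 sim_config(100, 1000, seed = 31, n_pcs = 0,
                                            weight_noise_ratio = 50))
  expect_lt(abs(cor(panel$beta_true, w_big$weight)), 0.15)

  # closed-form attenuation: corr = sqrt(var_b / (var_b + noise_sd^2))
  w1 <- simulate_gwas_weights(panel, cfg)
  vb <- var(panel$beta_true)
  nsd <- cfg$weight_noise_ratio * sd(panel$beta_true)
  expect_lt(abs(cor(panel$beta_true, w1$weight) - sqrt(vb / (vb + nsd^2))),
            0.1)
})

test_that("the whole generator is reproducible from its seed", {
  cfg <- sim_config(400, 20, seed = 77)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$panel, c2$panel)
  expect_identical(c1$genotypes$dosages, c2$genotypes$dosages)
  expect_identical(c1$phenotypes, c2$phenotypes)
  expect_identical(c1$followup, c2$followup)
  expect_identical(c1$weights, c2$weights)
})
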