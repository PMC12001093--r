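# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

# moderate synthetic cohort reused across cohort/GRS/MR tests
shared_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    cfg <- sim_config(6000, 60, seed = 101L)
    .fixtures$cohort <- simulate_cohort(cfg)
    .fixtures$config <- cfg
  }
  .fixtures$cohort
}

shared_config <- function() {
  invisible(shared_cohort())
  .fixtures$config
}

panel_alleles <- function(panel) {
  tibble::tibble(rsid = panel$rsid,
                 allele1 = panel$effect_allele,
                 allele2 = panel$other_allele)
}

# analysis table for the shared cohort after scoring and the genetic cascade
shared_analysis_data <- function() {
  if (is.null(.fixtures$analysis)) {
    co <- shared_cohort()
    harm <- harmonize_weights(co$weights, panel_alleles(co$panel))
    grs <- compute_grs(co$genotypes, harm)
    dat <- mr_input(co$phenotypes, co$followup, grs)
    .fixtures$analysis <- apply_exclusions(dat, "genetic")$data
  }
  .fixtures$analysis
}

# deterministic summary-statistic rows: by = slope * bx + pleiotropy + noise
make_summary_rows <- function(n_snp, slope, seed, se_x = 0.01, se_y = 0.05,
                              pleiotropy = rep(0, n_snp)) {
  withr::with_seed(seed, {
    bx_true <- runif(n_snp, 0.02, 0.15) * sample(c(-1, 1), n_snp, TRUE)
    tibble::tibble(
      rsid = sprintf("s%03d", seq_len(n_snp)),
      beta_exposure = rnorm(n_snp, bx_true, se_x),
      se_exposure = se_x,
      beta_outcome = rnorm(n_snp, slope * bx_true + pleiotropy, se_y),
      se_outcome = se_y
    )
  })
}
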