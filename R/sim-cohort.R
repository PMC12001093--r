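#' Simulate a complete synthetic cohort
#'
#' Runs the full generator chain — SNP panel, admixed genotypes, phenotypes
#' under the liability-threshold model, cause-specific mortality follow-up,
#' and an external-style GWAS weight file — and collects the generative truths
#' needed for parameter-recovery work.
#'
#' @param config A [sim_config()].
#' @return A `sim_cohort` list: `panel`, `genotypes`, `phenotypes`,
#'   `followup`, `weights`, and `truth` (true effects, true cause log rate
#'   ratios, the seed).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  panel <- simulate_panel(config)
  genotypes <- simulate_genotypes(panel, config)
  phenotypes <- simulate_phenotypes(genotypes, panel, config)
  followup <- simulate_mortality(phenotypes, config)
  weights <- simulate_gwas_weights(panel, config)
  structure(
    list(
      panel = panel,
      genotypes = genotypes,
      phenotypes = phenotypes,
      followup = followup,
      weights = weights,
      truth = list(
        beta_true = stats::setNames(panel$beta_true, panel$rsid),
        cause_log_rr = vapply(config$cause_hazards,
                              function(x) unname(x[["log_rr"]]), numeric(1)),
        seed = config$seed
      )
    ),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d individuals, %d SNPs, %d deaths\n",
              nrow(x$phenotypes), nrow(x$panel), sum(x$followup$died)))
  invisible(x)
}
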