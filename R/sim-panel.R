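#' Pathophysiological pathway labels
#'
#' The eight pathway groups used to partition T2D-associated instrument SNPs:
#' two beta-cell dysfunction groups (distinguished by the direction of their
#' proinsulin association), residual glycaemia, body fat, metabolic syndrome,
#' obesity-mediated insulin resistance, lipodystrophy, and liver/lipid
#' metabolism.
#'
#' @param n Number of labels wanted; beyond 8, generic labels are appended.
#' @return Character vector of length `n`.
#' @export
pathway_labels <- function(n = 8) {
  base <- c("beta_cell_proinsulin_pos", "beta_cell_proinsulin_neg",
            "residual_glycaemia", "body_fat", "metabolic_syndrome",
            "obesity_insulin_resistance", "lipodystrophy", "liver_lipid")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, paste0("pathway_", seq(length(base) + 1, n)))
}

# analytic variance of the true-weighted score under the admixture model:
# dosage_j | a ~ Binom(2, q_j(a)), q_j(a) = maf2_j + a * (maf1_j - maf2_j),
# a ~ Beta(ancestry_shape). Ancestry induces covariance across SNPs.
true_score_variance <- function(beta, maf1, maf2, ancestry_shape) {
  s1 <- ancestry_shape[1]; s2 <- ancestry_shape[2]
  mu_a <- s1 / (s1 + s2)
  var_a <- s1 * s2 / ((s1 + s2)^2 * (s1 + s2 + 1))
  delta <- maf1 - maf2
  eq <- maf2 + mu_a * delta
  eq2 <- maf2^2 + 2 * maf2 * delta * mu_a + delta^2 * (mu_a^2 + var_a)
  eq1q <- eq - eq2
  sum(beta^2 * (2 * eq1q + 4 * var_a * delta^2)) +
    4 * var_a * (sum(beta * delta)^2 - sum(beta^2 * delta^2))
}

#' Simulate the true instrument SNP panel
#'
#' Draws per-SNP ancestral allele frequencies (two source populations), allele
#' pairs (a configurable fraction strand-ambiguous, i.e. A/T or C/G), true
#' liability effects and pathway labels. True effects are scaled analytically
#' so that the population true-weighted score explains approximately
#' `grs_liability_r2` of total liability variance given the configured
#' confounder effects and unit residual liability noise.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per SNP: `rsid`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `maf_pop1`, `maf_pop2`, `beta_true`,
#'   `pathway`, `palindromic`, `strand`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_snps
  with_stage_seed(config$seed, 101L, {
    maf1 <- runif(m, config$maf_range[1], config$maf_range[2])
    maf2 <- pmin(pmax(maf1 + runif(m, -0.1, 0.1), config$maf_range[1]),
                 config$maf_range[2])
    palindromic <- runif(m) < config$palindromic_frac
    pal_pairs <- rbind(c("A", "T"), c("C", "G"))
    npal_pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
    pick <- function(pairs, k) {
      idx <- sample.int(nrow(pairs), k, replace = TRUE)
      swap <- runif(k) < 0.5
      ea <- ifelse(swap, pairs[idx, 2], pairs[idx, 1])
      oa <- ifelse(swap, pairs[idx, 1], pairs[idx, 2])
      cbind(ea, oa)
    }
    alleles <- matrix("", m, 2)
    if (any(palindromic)) alleles[palindromic, ] <- pick(pal_pairs, sum(palindromic))
    if (any(!palindromic)) alleles[!palindromic, ] <- pick(npal_pairs, sum(!palindromic))

    beta0 <- rnorm(m)
    if (config$grs_liability_r2 == 0) {
      beta <- rep(0, m)
    } else {
      var_conf <- sum(vapply(config$confounder_effects,
                             function(x) unname(x[["liability"]])^2, numeric(1)))
      target_var <- config$grs_liability_r2 / (1 - config$grs_liability_r2) *
        (var_conf + 1)
      v0 <- true_score_variance(beta0, maf1, maf2, config$ancestry_shape)
      beta <- beta0 * sqrt(target_var / v0)
    }
    pw <- sample(rep_len(pathway_labels(config$n_pathways), m))

    tibble(
      rsid = sprintf("rs%06d", seq_len(m)),
      chrom = sample(1:22, m, replace = TRUE),
      pos = sample.int(2e8, m),
      effect_allele = alleles[, 1],
      other_allele = alleles[, 2],
      maf_pop1 = maf1,
      maf_pop2 = maf2,
      beta_true = beta,
      pathway = pw,
      palindromic = palindromic,
      strand = "+"
    )
  })
}

#' Emulate an external GWAS weight file
#'
#' Estimated per-allele weights are the true liability effects plus Gaussian
#' noise whose SD is `weight_noise_ratio` times the SD of the true effects,
#' emulating estimation error in an external discovery GWAS of nominal finite
#' size. With the default ratio of 1 the expected correlation between true
#' effects and weights is 1/sqrt(2); the correlation between the weight file
#' and *in-cohort* per-allele estimates is lower still, mirroring the moderate
#' agreement typically seen between an external weight file and target-cohort
#' estimates.
#'
#' @param panel A panel from [simulate_panel()].
#' @param config A [sim_config()].
#' @return A SNP weight tibble: `rsid`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `weight`, `se`, `pathway`.
#' @export
simulate_gwas_weights <- function(panel, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(panel) == 0) abort("panel must be non-empty.")
  with_stage_seed(config$seed, 505L, {
    noise_sd <- config$weight_noise_ratio * stats::sd(panel$beta_true)
    if (!is.finite(noise_sd)) noise_sd <- 0
    tibble(
      rsid = panel$rsid,
      chrom = panel$chrom,
      pos = panel$pos,
      effect_allele = panel$effect_allele,
      other_allele = panel$other_allele,
      weight = panel$beta_true + rnorm(nrow(panel), 0, noise_sd),
      se = pmax(noise_sd, 1e-8),
      pathway = panel$pathway
    )
  })
}
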