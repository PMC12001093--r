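#' Simulate baseline phenotypes and covariates under a liability-threshold model
#'
#' Liability is the true-weighted genetic score plus the configured
#' (standardised) confounder contributions plus standard normal noise; T2D is
#' assigned above the empirical liability quantile matching the target
#' prevalence, so the realised prevalence matches under any confounder
#' configuration. Among cases, a configurable fraction is flagged previously
#' diagnosed (with a plausible diagnosis age and medication flags, and a small
#' likely-type-1 subset with diagnosis before age 35 plus insulin use); the
#' remainder are left for HbA1c-based detection. Covariates are drawn
#' independently of genotype. Genetic principal components are computed from
#' the centred dosage matrix by truncated eigendecomposition.
#'
#' @param genotypes A [simulate_genotypes()] result.
#' @param panel The matching panel.
#' @param config A [sim_config()].
#' @return A participant tibble; `score_true`, `liability_true`, `t2d_true`
#'   and the standardised `z_*` confounder columns (including the latent
#'   `z_conf_u`) are generator truths retained for parameter-recovery work,
#'   not observable study fields.
#' @export
simulate_phenotypes <- function(genotypes, panel, config) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "sim_genotypes"))
  if (!identical(colnames(genotypes$complete), panel$rsid)) {
    abort("genotypes and panel do not align.")
  }
  n <- nrow(genotypes$complete)
  with_stage_seed(config$seed, 303L, {
    s <- drop(genotypes$complete %*% panel$beta_true)

    sex <- factor(ifelse(runif(n) < config$female_frac, "women", "men"),
                  levels = c("men", "women"))
    age <- runif(n, config$age_range[1], config$age_range[2])
    district <- factor(sample(c("coyoacan", "iztapalapa"), n, TRUE,
                              prob = c(0.39, 0.61)))
    education <- factor(sample(c("university_or_high_school", "middle_school",
                                 "elementary", "other"), n, TRUE,
                               prob = c(0.16, 0.25, 0.45, 0.14)),
                        levels = c("university_or_high_school", "middle_school",
                                   "elementary", "other"))
    smoking <- factor(sample(c("never", "former", "occasional",
                               "lt10_per_day", "ge10_per_day"), n, TRUE,
                             prob = c(0.50, 0.21, 0.09, 0.12, 0.08)),
                      levels = c("never", "former", "occasional",
                                 "lt10_per_day", "ge10_per_day"))
    alcohol <- factor(sample(c("never", "former", "current"), n, TRUE,
                             prob = c(0.18, 0.14, 0.68)),
                      levels = c("never", "former", "current"))
    men <- sex == "men"
    height <- ifelse(men, rnorm(n, 165, 7), rnorm(n, 152, 6))
    bmi <- ifelse(men, rnorm(n, 28.0, 4.1), rnorm(n, 29.6, 5.1))
    bmi <- pmax(bmi, 13)
    weight <- bmi * (height / 100)^2
    waist <- ifelse(men, rnorm(n, 96, 10), rnorm(n, 93, 12))
    whr <- pmax(ifelse(men, rnorm(n, 0.95, 0.06), rnorm(n, 0.88, 0.06)), 0.6)
    hip <- waist / whr

    z <- list(
      age = zscore(age),
      bmi = zscore(bmi),
      smoking = zscore(as.numeric(smoking %in%
                                    c("occasional", "lt10_per_day", "ge10_per_day")))
    )
    conf <- rep(0, n)
    zcols <- list()
    for (nm in names(config$confounder_effects)) {
      col <- z[[nm]] %||% rnorm(n)  # unknown names become latent N(0,1) confounders
      zcols[[nm]] <- col
      conf <- conf + unname(config$confounder_effects[[nm]][["liability"]]) * col
    }

    liability <- s + conf + rnorm(n)
    if (stats::sd(liability) < 1e-12) {
      abort("degenerate liability distribution; target prevalence not achievable.")
    }
    thr <- stats::quantile(liability, 1 - config$target_prevalence, names = FALSE)
    t2d <- liability > thr

    diagnosed <- t2d & runif(n) < config$diagnosed_frac
    self_report <- diagnosed
    medication <- diagnosed & runif(n) < 0.8
    insulin <- diagnosed & runif(n) < 0.05
    diag_age <- rep(NA_real_, n)
    diag_age[diagnosed] <- pmax(30, age[diagnosed] - runif(sum(diagnosed), 0, 12))
    t1d <- diagnosed & runif(n) < config$t1d_frac
    diag_age[t1d] <- runif(sum(t1d), 10, 34)
    insulin[t1d] <- TRUE

    hba1c <- rnorm(n, config$hba1c_normal[["mean"]], config$hba1c_normal[["sd"]])
    undiag <- t2d & !diagnosed
    hba1c[diagnosed] <- rnorm(sum(diagnosed), config$hba1c_diagnosed[["mean"]],
                              config$hba1c_diagnosed[["sd"]])
    hba1c[undiag] <- rnorm(sum(undiag), config$hba1c_undiagnosed[["mean"]],
                           config$hba1c_undiagnosed[["sd"]])
    hba1c <- pmax(hba1c, 4)

    direct <- rep(0, n)
    for (pw in names(config$pathway_direct_effects)) {
      sp <- drop(genotypes$complete[, panel$pathway == pw, drop = FALSE] %*%
                   panel$beta_true[panel$pathway == pw])
      direct <- direct + config$pathway_direct_effects[[pw]] * zscore(sp)
    }

    out <- tibble(
      id = rownames(genotypes$complete),
      sex = sex, age = age, district = district, education = education,
      smoking = smoking, alcohol = alcohol,
      height_cm = height, weight_kg = weight, waist_cm = waist, hip_cm = hip,
      bmi = bmi, hba1c = hba1c,
      self_report_diabetes = self_report,
      diabetes_medication = medication,
      insulin = insulin,
      diag_age = diag_age,
      prior_ihd = runif(n) < 0.012,
      prior_stroke = runif(n) < 0.009,
      prior_ckd = runif(n) < 0.008,
      prior_cirrhosis = runif(n) < 0.0013,
      prior_cancer = runif(n) < 0.011,
      prior_emphysema = runif(n) < 0.002,
      ancestry = genotypes$ancestry$ancestry,
      relatedness = "unrelated",
      genetic_missing = FALSE,
      duplicate = FALSE,
      score_true = s,
      liability_true = liability,
      t2d_true = t2d,
      direct_hazard_true = direct
    )
    for (nm in names(zcols)) out[[paste0("z_", nm)]] <- zcols[[nm]]

    if (config$n_pcs > 0) {
      pcs <- dosage_pcs(genotypes$dosages, config$n_pcs)
      for (k in seq_len(ncol(pcs))) out[[paste0("pc", k)]] <- pcs[, k]
    }
    out
  })
}

# top-k principal components of a centred (mean-imputed) dosage matrix via
# eigendecomposition of the SNP-by-SNP cross-product
dosage_pcs <- function(dosages, k) {
  x <- dosages
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  x <- sweep(x, 2, colMeans(x))
  k <- min(k, ncol(x) - 1, nrow(x) - 1)
  ev <- eigen(crossprod(x), symmetric = TRUE)
  pcs <- x %*% ev$vectors[, seq_len(k), drop = FALSE]
  colnames(pcs) <- paste0("pc", seq_len(k))
  pcs
}
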