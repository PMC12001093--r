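#' Per-SNP mortality scan
#'
#' Age-band x sex stratified Cox association of each SNP with all-cause
#' mortality, the outcome side of the two-sample sensitivity suite. Missing
#' dosages are mean-imputed; monomorphic SNPs are skipped.
#'
#' @param dosages Individuals x SNPs matrix (rownames = ids).
#' @param data Analysis tibble with `id`, `sex`, `entry_age`, `exit_age`,
#'   `died` (and optionally PCs).
#' @param breaks Age grid.
#' @param pcs PC adjustment columns (those present are used).
#' @return Tibble: `rsid`, `beta`, `se`, `status`.
#' @export
per_allele_cox_scan <- function(dosages, data, breaks = seq(35, 75, 5),
                                pcs = character(0)) {
  pcs <- intersect(pcs, names(data))
  keep <- c("id", "sex", pcs, "entry_age", "exit_age", "died")
  ep <- lexis_expand(data[keep], breaks)
  m <- ncol(dosages)
  beta <- se <- rep(NA_real_, m)
  status <- rep("ok", m)
  idx <- match(ep$id, rownames(dosages))
  for (j in seq_len(m)) {
    x <- dosages[, j]
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    if (stats::sd(x) == 0) {
      status[j] <- "monomorphic"
      next
    }
    ep$snp <- x[idx]
    fit <- tryCatch(
      fit_stratified_cox(ep, "snp", covariates = pcs,
                         strata = c("age_band", "sex")),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      status[j] <- "fit_failed"
      next
    }
    beta[j] <- fit$beta
    se[j] <- fit$se
  }
  tibble(rsid = colnames(dosages) %||% as.character(seq_len(m)),
         beta = beta, se = se, status = status)
}

#' Build the two-sample summary-statistic table
#'
#' Joins the external exposure-side weights (per-allele log odds of T2D with
#' SEs) to in-cohort outcome-side per-allele estimates. The assumption of no
#' overlap between the exposure and outcome populations is the caller's to
#' assert; it is documented, not enforced.
#'
#' @param weights Weight tibble with `rsid`, `weight`, `se`.
#' @param outcome_scan Tibble from [per_allele_cox_scan()].
#' @return Summary rows for [mr_ivw()] and friends.
#' @export
summary_stats_rows <- function(weights, outcome_scan) {
  assert_cols(weights, c("rsid", "weight", "se"), "weights")
  ok <- outcome_scan$status == "ok"
  dplyr::inner_join(
    tibble(rsid = weights$rsid, beta_exposure = weights$weight,
           se_exposure = weights$se),
    tibble(rsid = outcome_scan$rsid[ok], beta_outcome = outcome_scan$beta[ok],
           se_outcome = outcome_scan$se[ok]),
    by = "rsid"
  )
}

#' Run the end-to-end synthetic pipeline
#'
#' Simulate -> harmonise and score -> assemble (classification,
#' re-attribution, eligibility cascade) -> one-sample MR per cause ->
#' optional observational comparison and two-sample sensitivity suite.
#' A manifest (package version, seed, config hash) makes any bundle
#' reproducible: re-running with the same config yields identical tables.
#'
#' @param config A [sim_config()].
#' @param causes Cause groups to analyse.
#' @param k Reporting base for predicted odds.
#' @param se_method Wald-ratio SE method.
#' @param observational Run the observational comparison.
#' @param sensitivity Run the per-SNP scans and summary-statistic suite
#'   (adds one Cox fit per SNP).
#' @param out_dir Optional directory to write result tables into.
#' @return An `mr_bundle` list with the cohort, ledgers, fitted results and
#'   manifest.
#' @export
run_pipeline <- function(config,
                         causes = default_causes(),
                         k = 3,
                         se_method = "simple",
                         observational = TRUE,
                         sensitivity = FALSE,
                         out_dir = NULL) {
  cohort <- simulate_cohort(config)
  alleles <- tibble(rsid = cohort$panel$rsid,
                    allele1 = cohort$panel$effect_allele,
                    allele2 = cohort$panel$other_allele)
  harm <- harmonize_weights(cohort$weights, alleles)
  grs <- compute_grs(cohort$genotypes, harm)
  data <- mr_input(cohort$phenotypes, cohort$followup, grs)

  gen <- apply_exclusions(data, "genetic")
  mr <- run_one_sample_mr(gen$data, causes = causes, k = k,
                          se_method = se_method)

  obs <- NULL; obs_ledger <- NULL
  if (observational) {
    obs_x <- apply_exclusions(data, "observational")
    obs <- observational_mortality(obs_x$data, causes = causes)
    obs_ledger <- obs_x$ledger
  }

  sens <- NULL
  if (sensitivity) {
    scan <- per_allele_cox_scan(
      cohort$genotypes$dosages[gen$data$id, , drop = FALSE], gen$data)
    rows <- summary_stats_rows(harm$weights, scan)
    sens <- mr_sensitivity_suite(rows, seed = config$seed)
  }

  manifest <- list(
    package = "mrmort",
    version = as.character(utils::packageVersion("mrmort")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config))
  )
  bundle <- structure(
    list(cohort = cohort, harmonization = harm, grs = grs,
         analysis_data = data, genetic_ledger = gen$ledger,
         observational_ledger = obs_ledger,
         mr_results = mr, observational_results = obs,
         sensitivity = sens, manifest = manifest),
    class = "mr_bundle"
  )
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.mr_bundle <- function(x, ...) {
  cat(sprintf("<mr_bundle> seed %d, %d individuals analysed, %d causes\n",
              x$manifest$seed, nrow(x$analysis_data), nrow(x$mr_results)))
  invisible(x)
}

#' Write an analysis bundle to disk
#'
#' Result tables as TSV, ledgers and manifest as JSON.
#'
#' @param bundle An `mr_bundle`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(as_tibble(bundle$mr_results),
                   file.path(out_dir, "mr_results.tsv"), progress = FALSE)
  if (!is.null(bundle$observational_results)) {
    readr::write_tsv(as_tibble(bundle$observational_results),
                     file.path(out_dir, "observational_results.tsv"),
                     progress = FALSE)
  }
  if (!is.null(bundle$sensitivity)) {
    readr::write_tsv(bundle$sensitivity,
                     file.path(out_dir, "sensitivity.tsv"), progress = FALSE)
  }
  ledgers <- list(
    genetic = c(list(initial = attr(bundle$genetic_ledger, "initial"),
                     remaining = attr(bundle$genetic_ledger, "remaining")),
                stats::setNames(as.list(bundle$genetic_ledger$n_excluded),
                                bundle$genetic_ledger$reason))
  )
  if (!is.null(bundle$observational_ledger)) {
    ledgers$observational <-
      c(list(initial = attr(bundle$observational_ledger, "initial"),
             remaining = attr(bundle$observational_ledger, "remaining")),
        stats::setNames(as.list(bundle$observational_ledger$n_excluded),
                        bundle$observational_ledger$reason))
  }
  jsonlite::write_json(ledgers, file.path(out_dir, "ledgers.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    c(bundle$manifest,
      list(exclusions = stats::setNames(
        as.list(bundle$harmonization$exclusions$n),
        bundle$harmonization$exclusions$reason))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
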