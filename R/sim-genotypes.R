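#' Simulate admixed genotype dosages
#'
#' Each individual receives an admixture fraction `a` drawn from the
#' configured Beta distribution; each dosage is two allele draws at the
#' individual-specific mixed frequency `maf_pop2 + a * (maf_pop1 - maf_pop2)`.
#' Missing dosages are injected completely at random at `missing_rate`.
#'
#' @param panel A panel from [simulate_panel()].
#' @param config A [sim_config()].
#' @return A `sim_genotypes` object: a list with `dosages` (individuals x SNPs
#'   numeric matrix, `NA` where missing), `complete` (the pre-missingness
#'   matrix, used by the phenotype generator as the genetic truth), and
#'   `ancestry` (tibble of `id`, `ancestry`).
#' @export
simulate_genotypes <- function(panel, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(panel) == 0) abort("panel must be non-empty.")
  n <- config$n_individuals
  m <- nrow(panel)
  with_stage_seed(config$seed, 202L, {
    a <- stats::rbeta(n, config$ancestry_shape[1], config$ancestry_shape[2])
    delta <- panel$maf_pop1 - panel$maf_pop2
    q <- outer(a, delta) + matrix(panel$maf_pop2, n, m, byrow = TRUE)
    d <- matrix(rbinom(n * m, 2L, q), n, m)
    rm(q)
    storage.mode(d) <- "double"
    ids <- sprintf("id%07d", seq_len(n))
    dimnames(d) <- list(ids, panel$rsid)
    if (config$missing_rate > 0) {
      masked <- d
      masked[runif(n * m) < config$missing_rate] <- NA_real_
    } else {
      masked <- d
    }
    structure(
      list(dosages = masked,
           complete = d,
           ancestry = tibble(id = ids, ancestry = a)),
      class = "sim_genotypes"
    )
  })
}

#' @export
print.sim_genotypes <- function(x, ...) {
  cat(sprintf("<sim_genotypes> %d individuals x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}
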