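is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonise external SNP weights against genotype alleles
#'
#' SNPs absent from the genotype data are dropped and counted "unavailable";
#' strand-ambiguous (palindromic, A/T or C/G) SNPs are dropped and counted
#' "ambiguous"; SNPs whose effect allele matches the genotype's counted allele
#' keep their weight; SNPs with swapped alleles are flagged for dosage
#' flipping (d -> 2 - d); irreconcilable allele pairs are dropped with reason
#' "mismatch", never silently scored.
#'
#' @param weights SNP weight tibble with `rsid`, `effect_allele`,
#'   `other_allele`, `weight` (and optionally `pathway`, `se`).
#' @param genotype_alleles Tibble with `rsid`, `allele1` (the allele counted
#'   by the dosage), `allele2`.
#' @return A `grs_harmonization` object: list with `weights` (aligned tibble
#'   including a `flip` flag) and `exclusions` (tibble of `reason`, `n`).
#' @export
harmonize_weights <- function(weights, genotype_alleles) {
  assert_cols(weights, c("rsid", "effect_allele", "other_allele", "weight"),
              "weights")
  assert_cols(genotype_alleles, c("rsid", "allele1", "allele2"),
              "genotype_alleles")
  bases <- c("A", "C", "G", "T")
  if (!all(weights$effect_allele %in% bases & weights$other_allele %in% bases)) {
    abort("weight alleles must be single bases A/C/G/T.")
  }
  if (!all(genotype_alleles$allele1 %in% bases &
           genotype_alleles$allele2 %in% bases)) {
    abort("genotype alleles must be single bases A/C/G/T.")
  }

  avail <- weights$rsid %in% genotype_alleles$rsid
  n_unavailable <- sum(!avail)
  w <- weights[avail, , drop = FALSE]

  pal <- is_palindromic(w$effect_allele, w$other_allele)
  n_ambiguous <- sum(pal)
  w <- w[!pal, , drop = FALSE]

  g <- genotype_alleles[match(w$rsid, genotype_alleles$rsid), ]
  same <- w$effect_allele == g$allele1 & w$other_allele == g$allele2
  swapped <- w$effect_allele == g$allele2 & w$other_allele == g$allele1
  n_mismatch <- sum(!same & !swapped)
  keep <- same | swapped
  aligned <- w[keep, , drop = FALSE]
  aligned$flip <- swapped[keep]

  structure(
    list(
      weights = as_tibble(aligned),
      exclusions = tibble(
        reason = c("unavailable", "ambiguous", "mismatch"),
        n = c(n_unavailable, n_ambiguous, n_mismatch)
      )
    ),
    class = "grs_harmonization"
  )
}

#' @export
print.grs_harmonization <- function(x, ...) {
  cat(sprintf("<grs_harmonization> %d SNPs scored; excluded: %s\n",
              nrow(x$weights),
              paste(sprintf("%s %d", x$exclusions$reason, x$exclusions$n),
                    collapse = ", ")))
  invisible(x)
}

#' @export
tidy.grs_harmonization <- function(x, ...) x$exclusions

resolve_weights <- function(weights) {
  if (inherits(weights, "grs_harmonization")) weights <- weights$weights
  if (!"flip" %in% names(weights)) weights$flip <- FALSE
  weights
}

#' Compute a genetic risk score
#'
#' `score_i = sum_j w_j d_ij` over harmonised SNPs, with flipped SNPs scored
#' on `2 - d`. Missing dosages are imputed as twice the effect-allele
#' frequency estimated from non-missing individuals (mean imputation,
#' unbiased under missingness at random); SNPs with 100% missingness are
#' dropped with a warning.
#'
#' @param dosages Individuals x SNPs numeric matrix (rsid column names,
#'   `NA` for missing), or a [simulate_genotypes()] result.
#' @param weights A `grs_harmonization` or an aligned weight tibble.
#' @return A `grs_result` tibble: `id`, `score`, `score_std` (per-SD), with
#'   attributes `score_sd` and `n_snps`.
#' @export
compute_grs <- function(dosages, weights) {
  if (inherits(dosages, "sim_genotypes")) dosages <- dosages$dosages
  w <- resolve_weights(weights)
  w <- w[w$rsid %in% colnames(dosages), , drop = FALSE]
  if (nrow(w) == 0) abort("empty instrument: no harmonised SNPs present in the dosage matrix.")

  d <- dosages[, w$rsid, drop = FALSE]
  if (any(w$flip)) {
    d[, w$flip] <- 2 - d[, w$flip, drop = FALSE]
  }
  all_missing <- colSums(!is.na(d)) == 0
  if (any(all_missing)) {
    warn(sprintf("dropping %d SNP(s) with 100%% missing dosages: %s",
                 sum(all_missing),
                 paste(head(colnames(d)[all_missing], 5), collapse = ", ")))
    d <- d[, !all_missing, drop = FALSE]
    w <- w[!all_missing, , drop = FALSE]
    if (nrow(w) == 0) abort("empty instrument after dropping fully missing SNPs.")
  }
  if (anyNA(d)) {
    eaf <- colMeans(d, na.rm = TRUE) / 2
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- 2 * eaf[idx[, 2]]
  }
  score <- unname(drop(d %*% w$weight))
  s <- stats::sd(score)
  out <- tibble(
    id = rownames(dosages) %||% as.character(seq_len(nrow(dosages))),
    score = score,
    score_std = if (s > 0) (score - mean(score)) / s else score * 0
  )
  attr(out, "score_sd") <- s
  attr(out, "n_snps") <- nrow(w)
  class(out) <- c("grs_result", class(out))
  out
}

#' Per-pathway genetic risk scores
#'
#' Each pathway score uses only its own SNPs; the pathways partition the
#' scored SNPs, so when they cover all SNPs the pathway scores sum to the
#' total score. No minimum size is enforced, but pathways with fewer than
#' `min_snps` variants carry a small-instrument warning flag (legitimate:
#' a liver/lipid-type pathway can hold just 2 SNPs).
#'
#' @param dosages As in [compute_grs()].
#' @param weights A `grs_harmonization` or aligned weight tibble with a
#'   `pathway` column.
#' @param min_snps Threshold below which a pathway is flagged small.
#' @return A long tibble: `pathway`, `id`, `score`, `score_std`, `n_snps`,
#'   `small_instrument`.
#' @export
pathway_scores <- function(dosages, weights, min_snps = 5) {
  w <- resolve_weights(weights)
  assert_cols(w, "pathway", "weights")
  if (anyNA(w$pathway)) abort("unknown (missing) pathway label on scored SNPs.")
  purrr::map_dfr(split(w, w$pathway), function(wp) {
    g <- compute_grs(dosages, wp)
    tibble(
      pathway = wp$pathway[1],
      id = g$id,
      score = g$score,
      score_std = g$score_std,
      n_snps = attr(g, "n_snps"),
      small_instrument = attr(g, "n_snps") < min_snps
    )
  })
}

#' Assign near-equal-sized quantile bins
#'
#' Bins individuals into `k` groups of the score distribution; ties are broken
#' by stable input order, so bin sizes differ by at most 1 even when scores
#' are tied.
#'
#' @param scores Numeric vector.
#' @param k Number of bins (>= 2).
#' @return Integer vector of bin indices in `1:k`.
#' @export
quantile_bins <- function(scores, k) {
  if (k < 2) abort("`k` must be at least 2.")
  n <- length(scores)
  if (k > n) abort("`k` cannot exceed the number of scores.")
  r <- rank(scores, ties.method = "first")
  as.integer(ceiling(r * k / n))
}
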