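ivw_point <- function(bx, by, w) {
  sxx <- sum(w * bx^2)
  list(estimate = sum(w * bx * by) / sxx, se = sqrt(1 / sxx))
}

# leave-one-out IVW slopes from precomputed weighted sums
loo_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Detects and removes SNPs with heterogeneous (potentially pleiotropic)
#' effects. The global test compares the observed weighted residual sum of
#' squares around leave-one-out IVW fits with its parametric null
#' distribution (exposure and outcome effects redrawn from per-SNP normal
#' models); per-SNP outlier p-values are Bonferroni-corrected at `threshold`;
#' a corrected IVW estimate is computed on the retained set; and a distortion
#' test compares the full-set and outlier-corrected estimates against a null
#' of random exclusion sets of the same size (this implementation's variant
#' of the distortion null).
#'
#' @param rows Summary-statistic tibble as in [mr_ivw()]; at least 4 SNPs.
#' @param n_sim Number of parametric simulations (>= 100).
#' @param threshold Significance level for the outlier test (Bonferroni
#'   corrected across SNPs).
#' @param seed Simulation seed.
#' @return An `mr_presso` object: global RSS and p, per-SNP outlier
#'   p-values, outlier list, raw and outlier-corrected IVW estimates (the
#'   corrected estimate is absent iff no outliers), and the distortion test.
#' @export
mr_presso <- function(rows, n_sim = 1000, threshold = 0.05, seed = 1L) {
  check_summary_rows(rows, 4)
  if (n_sim < 100) abort("`n_sim` must be at least 100.")
  n <- nrow(rows)
  rsid <- rows[["rsid"]] %||% as.character(seq_len(n))
  # orient exposure effects positive so results are invariant (bit-for-bit)
  # to flipping any row's allele orientation
  flip <- sign(rows$beta_exposure)
  flip[flip == 0] <- 1
  bx <- rows$beta_exposure * flip
  by <- rows$beta_outcome * flip
  sx <- rows$se_exposure; sy <- rows$se_outcome
  w <- 1 / sy^2

  b_loo <- loo_slopes(bx, by, w)
  e_obs <- w * (by - b_loo * bx)^2
  rss_obs <- sum(e_obs)

  sims <- with_stage_seed(seed, 0L, {
    bx_s <- matrix(rnorm(n * n_sim, bx, sx), n, n_sim)
    by_s <- matrix(rnorm(n * n_sim, b_loo * bx, sy), n, n_sim)
    sxy_s <- colSums(w * bx_s * by_s)
    sxx_s <- colSums(w * bx_s^2)
    bloo_s <- (rep(sxy_s, each = n) - w * bx_s * by_s) /
      (rep(sxx_s, each = n) - w * bx_s^2)
    e_s <- w * (by_s - bloo_s * bx_s)^2
    list(e = e_s, rss = colSums(e_s))
  })

  global_p <- (1 + sum(sims$rss >= rss_obs)) / (n_sim + 1)
  outlier_p <- rowMeans(sims$e >= e_obs)
  outliers <- which(outlier_p < threshold / n)

  raw <- ivw_point(bx, by, w)
  corrected <- NULL
  distortion <- NA_real_
  distortion_p <- NA_real_
  if (length(outliers) > 0 && length(outliers) < n - 1) {
    keep <- setdiff(seq_len(n), outliers)
    corrected <- ivw_point(bx[keep], by[keep], w[keep])
    distortion <- (raw$estimate - corrected$estimate) / abs(corrected$estimate)
    d_null <- with_stage_seed(seed, 1L, {
      vapply(seq_len(n_sim), function(s) {
        drop_s <- sample.int(n, length(outliers))
        sub <- ivw_point(bx[-drop_s], by[-drop_s], w[-drop_s])
        (raw$estimate - sub$estimate) / abs(sub$estimate)
      }, numeric(1))
    })
    distortion_p <- mean(abs(d_null) >= abs(distortion))
  }

  structure(
    list(global_rss = rss_obs, global_p = global_p,
         outlier_p = stats::setNames(outlier_p, rsid),
         outliers = rsid[outliers],
         raw_estimate = raw, corrected_estimate = corrected,
         distortion = distortion, distortion_p = distortion_p,
         n_snp = n, n_sim = n_sim, threshold = threshold, seed = seed),
    class = "mr_presso"
  )
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("<mr_presso> global RSS %.3f (p = %.3g), %d SNPs, %d outlier(s)\n",
              x$global_rss, x$global_p, x$n_snp, length(x$outliers)))
  if (length(x$outliers)) {
    cat(sprintf("  outliers: %s\n", paste(x$outliers, collapse = ", ")))
    cat(sprintf("  raw beta %.4f -> corrected %.4f (distortion p = %.3g)\n",
                x$raw_estimate$estimate, x$corrected_estimate$estimate,
                x$distortion_p))
  }
  invisible(x)
}

#' @export
tidy.mr_presso <- function(x, ...) {
  out <- tibble(term = "raw", estimate = x$raw_estimate$estimate,
                std.error = x$raw_estimate$se)
  if (!is.null(x$corrected_estimate)) {
    out <- dplyr::bind_rows(out,
      tibble(term = "outlier_corrected",
             estimate = x$corrected_estimate$estimate,
             std.error = x$corrected_estimate$se))
  }
  out
}

#' @export
glance.mr_presso <- function(x, ...) {
  tibble(global_rss = x$global_rss, global_p = x$global_p,
         n_outliers = length(x$outliers), distortion = x$distortion,
         distortion_p = x$distortion_p, n_snp = x$n_snp, n_sim = x$n_sim,
         seed = x$seed)
}
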