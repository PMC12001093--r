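check_summary_rows <- function(rows, min_rows) {
  assert_cols(rows, c("beta_exposure", "se_exposure", "beta_outcome",
                      "se_outcome"), "summary rows")
  if (nrow(rows) < min_rows) {
    abort(sprintf("at least %d SNPs are required.", min_rows))
  }
  if (any(rows$se_exposure <= 0) || any(rows$se_outcome <= 0)) {
    abort("standard errors must be positive.")
  }
  rows
}

#' Inverse-variance weighted estimator
#'
#' Weighted regression of SNP-outcome on SNP-exposure effects through the
#' origin with weights `1/se_outcome^2`; assumes every SNP is a valid
#' instrument. The random-effects model inflates the SE by
#' `max(1, sqrt(Q/(n-1)))` where Q is Cochran's heterogeneity statistic.
#'
#' @param rows Summary-statistic tibble: `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome` (an `rsid` column is carried if present).
#' @param model `"random"` (default) or `"fixed"`.
#' @return An `mr_ivw` object.
#' @export
mr_ivw <- function(rows, model = c("random", "fixed")) {
  model <- match.arg(model)
  check_summary_rows(rows, 2 - (model == "fixed"))
  w <- 1 / rows$se_outcome^2
  bx <- rows$beta_exposure; by <- rows$beta_outcome
  sxx <- sum(w * bx^2)
  est <- sum(w * bx * by) / sxx
  se <- sqrt(1 / sxx)
  n <- nrow(rows)
  q <- sum(w * (by - est * bx)^2)
  if (model == "random" && n > 1) {
    se <- se * max(1, sqrt(q / (n - 1)))
  }
  structure(
    list(estimate = est, se = se, n_snp = n, model = model,
         q = q, q_df = max(n - 1, 0),
         q_p = if (n > 1) stats::pchisq(q, n - 1, lower.tail = FALSE) else NA_real_),
    class = "mr_ivw"
  )
}

#' @export
print.mr_ivw <- function(x, ...) {
  cat(sprintf("<mr_ivw:%s> beta %.4f (se %.4f), %d SNPs, Q = %.2f (p = %.3g)\n",
              x$model, x$estimate, x$se, x$n_snp, x$q, x$q_p))
  invisible(x)
}

#' @export
tidy.mr_ivw <- function(x, ...) {
  tibble(term = "beta", estimate = x$estimate, std.error = x$se,
         statistic = x$estimate / x$se,
         p.value = 2 * pnorm(-abs(x$estimate / x$se)))
}

#' @export
glance.mr_ivw <- function(x, ...) {
  tibble(n_snp = x$n_snp, model = x$model, q = x$q, q_df = x$q_df, q_p = x$q_p)
}

#' MR-Egger regression
#'
#' Weighted linear regression of SNP-outcome on SNP-exposure effects with a
#' free intercept (weights `1/se_outcome^2`); a nonzero intercept indicates
#' directional pleiotropy while the slope remains a pleiotropy-robust causal
#' estimate under the InSIDE assumption. Rows are first oriented so every
#' exposure effect is positive. The SE uses a multiplicative dispersion
#' bounded below by 1.
#'
#' @param rows As in [mr_ivw()]; at least 3 SNPs.
#' @return An `mr_egger` object with slope and intercept estimates.
#' @export
mr_egger <- function(rows) {
  check_summary_rows(rows, 3)
  flip <- sign(rows$beta_exposure)
  flip[flip == 0] <- 1
  bx <- rows$beta_exposure * flip
  by <- rows$beta_outcome * flip
  if (stats::sd(bx) == 0) {
    abort("collinear design: all exposure effects are equal.")
  }
  w <- 1 / rows$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  disp <- max(1, sm$sigma)
  cf <- sm$coefficients
  slope <- cf["bx", "Estimate"]
  slope_se <- cf["bx", "Std. Error"] / sm$sigma * disp
  inter <- cf["(Intercept)", "Estimate"]
  inter_se <- cf["(Intercept)", "Std. Error"] / sm$sigma * disp
  structure(
    list(estimate = slope, se = slope_se,
         intercept = inter, intercept_se = inter_se,
         intercept_p = 2 * pnorm(-abs(inter / inter_se)),
         n_snp = nrow(rows)),
    class = "mr_egger"
  )
}

#' @export
print.mr_egger <- function(x, ...) {
  cat(sprintf("<mr_egger> slope %.4f (se %.4f); intercept %.5f (se %.5f, p = %.3g); %d SNPs\n",
              x$estimate, x$se, x$intercept, x$intercept_se, x$intercept_p,
              x$n_snp))
  invisible(x)
}

#' @export
tidy.mr_egger <- function(x, ...) {
  tibble(term = c("slope", "intercept"),
         estimate = c(x$estimate, x$intercept),
         std.error = c(x$se, x$intercept_se),
         statistic = c(x$estimate / x$se, x$intercept / x$intercept_se)) |>
    mutate(p.value = 2 * pnorm(-abs(.data$statistic)))
}

#' @export
glance.mr_egger <- function(x, ...) tibble(n_snp = x$n_snp)

weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  ww <- w[ord] / sum(w)
  cum <- cumsum(ww) - ww / 2
  if (cum[1] >= 0.5) return(r[1])
  if (cum[length(cum)] <= 0.5) return(r[length(r)])
  below <- max(which(cum < 0.5))
  r[below] + (r[below + 1] - r[below]) *
    (0.5 - cum[below]) / (cum[below + 1] - cum[below])
}

#' Weighted median estimator
#'
#' The inverse-variance weight-interpolated 50th percentile of the per-SNP
#' Wald ratios; consistent when at least half of the weight comes from valid
#' instruments. The SE comes from a seeded parametric bootstrap.
#'
#' @param rows As in [mr_ivw()]; at least 3 SNPs.
#' @param n_boot Number of bootstrap draws.
#' @param seed Bootstrap seed.
#' @return An `mr_wmedian` object.
#' @export
mr_weighted_median <- function(rows, n_boot = 1000, seed = 1L) {
  check_summary_rows(rows, 3)
  ratio <- rows$beta_outcome / rows$beta_exposure
  w <- rows$beta_exposure^2 / rows$se_outcome^2
  est <- weighted_median_point(ratio, w)
  boot <- with_stage_seed(seed, 0L, {
    vapply(seq_len(n_boot), function(i) {
      bx <- rnorm(nrow(rows), rows$beta_exposure, rows$se_exposure)
      by <- rnorm(nrow(rows), rows$beta_outcome, rows$se_outcome)
      weighted_median_point(by / bx, bx^2 / rows$se_outcome^2)
    }, numeric(1))
  })
  structure(
    list(estimate = est, se = stats::sd(boot), n_snp = nrow(rows),
         n_boot = n_boot, seed = seed),
    class = "mr_wmedian"
  )
}

#' @export
print.mr_wmedian <- function(x, ...) {
  cat(sprintf("<mr_wmedian> beta %.4f (bootstrap se %.4f), %d SNPs\n",
              x$estimate, x$se, x$n_snp))
  invisible(x)
}

#' @export
tidy.mr_wmedian <- function(x, ...) {
  tibble(term = "beta", estimate = x$estimate, std.error = x$se,
         statistic = x$estimate / x$se,
         p.value = 2 * pnorm(-abs(x$estimate / x$se)))
}

#' @export
glance.mr_wmedian <- function(x, ...) {
  tibble(n_snp = x$n_snp, n_boot = x$n_boot, seed = x$seed)
}

#' Run the two-sample sensitivity suite
#'
#' IVW, MR-Egger, weighted median and MR-PRESSO on one summary-statistic
#' table, returned as a tidy comparison.
#'
#' @param rows As in [mr_ivw()].
#' @param n_boot Bootstrap draws for the weighted median.
#' @param n_sim Simulations for MR-PRESSO.
#' @param seed Seed for the stochastic methods.
#' @return Tibble with one row per method.
#' @export
mr_sensitivity_suite <- function(rows, n_boot = 1000, n_sim = 1000, seed = 1L) {
  ivw <- mr_ivw(rows)
  egger <- mr_egger(rows)
  wm <- mr_weighted_median(rows, n_boot = n_boot, seed = seed)
  pr <- mr_presso(rows, n_sim = n_sim, seed = seed)
  pr_est <- pr$corrected_estimate %||% pr$raw_estimate
  dplyr::bind_rows(
    tibble(method = "ivw", estimate = ivw$estimate, se = ivw$se),
    tibble(method = "mr_egger", estimate = egger$estimate, se = egger$se),
    tibble(method = "weighted_median", estimate = wm$estimate, se = wm$se),
    tibble(method = "mr_presso", estimate = pr_est$estimate, se = pr_est$se)
  ) |>
    mutate(conf.low = .data$estimate - 1.96 * .data$se,
           conf.high = .data$estimate + 1.96 * .data$se)
}
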