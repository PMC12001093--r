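new_mr_estimate <- function(logrr, se, base, cause = NA_character_,
                            n_events = NA_integer_, se_method = "simple",
                            weak_instrument = FALSE) {
  structure(
    list(logrr = logrr, se = se, base = base, cause = cause,
         n_events = n_events, se_method = se_method,
         weak_instrument = weak_instrument),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  ci <- x$logrr + c(-1.96, 1.96) * x$se
  cat(sprintf("<mr_estimate> RR %.3f (95%% CI %.3f-%.3f) per %.3g-fold increase in predicted odds\n",
              exp(x$logrr), exp(ci[1]), exp(ci[2]), x$base))
  if (isTRUE(x$weak_instrument)) cat("  (weak-instrument warning attached)\n")
  invisible(x)
}

#' @export
tidy.mr_estimate <- function(x, ...) {
  tibble(cause = x$cause, logrr = x$logrr, se = x$se,
         rr = exp(x$logrr),
         conf.low = exp(x$logrr - 1.96 * x$se),
         conf.high = exp(x$logrr + 1.96 * x$se),
         base = x$base, n_events = x$n_events,
         weak_instrument = x$weak_instrument)
}

#' Ratio-of-coefficients (Wald) Mendelian randomisation estimator
#'
#' Divides the score-outcome association by the score-exposure association;
#' the result is a log rate ratio per 1-unit increase in genetically-predicted
#' log-odds of the exposure, i.e. per e-fold (base ~2.72) increase in
#' predicted odds. The SE is either the numerator SE scaled by the exposure
#' coefficient ("simple", appropriate with a strong instrument) or the
#' two-term first-order delta propagation assuming independent errors.
#'
#' @param grs_outcome `assoc_estimate` for score-outcome (log hazard ratio per
#'   score unit).
#' @param grs_exposure `assoc_estimate` for score-exposure (log odds ratio per
#'   score unit, same score scale).
#' @param se_method `"simple"` or `"delta"`.
#' @param weak_z Instrument-strength threshold: if `|beta_exp|/se_exp` is
#'   below it a weak-instrument flag is attached (with a warning).
#' @return An `mr_estimate` with base e.
#' @export
wald_ratio <- function(grs_outcome, grs_exposure,
                       se_method = c("simple", "delta"), weak_z = 10) {
  se_method <- match.arg(se_method)
  b_out <- grs_outcome$beta; se_out <- grs_outcome$se
  b_exp <- grs_exposure$beta; se_exp <- grs_exposure$se
  if (b_exp == 0) abort("exposure coefficient is zero; the Wald ratio is undefined.")
  weak <- abs(b_exp) / se_exp < weak_z
  if (weak) {
    warn(sprintf("weak instrument: |beta_exposure|/se = %.2f < %g",
                 abs(b_exp) / se_exp, weak_z))
  }
  ratio <- b_out / b_exp
  se <- switch(se_method,
    simple = se_out / abs(b_exp),
    delta = sqrt(se_out^2 / b_exp^2 + b_out^2 * se_exp^2 / b_exp^4)
  )
  new_mr_estimate(ratio, se, base = exp(1),
                  n_events = grs_outcome$n_events,
                  se_method = se_method, weak_instrument = weak)
}

#' Rescale an MR estimate to a k-fold increase in predicted odds
#'
#' Multiplies the log rate ratio and its SE by `log(k) / log(current base)`;
#' rescaling from base e to a trebling multiplies by ln 3 (~1.10). The
#' operation is an exact group action: rescaling twice equals rescaling once
#' to the final base, and CI endpoints transform with the point estimate.
#'
#' @param estimate An `mr_estimate`.
#' @param k New base (> 1), e.g. 3 for per-trebling, 2 for per-doubling.
#' @return The rescaled `mr_estimate`.
#' @export
rescale_base <- function(estimate, k) {
  if (!is.numeric(k) || length(k) != 1 || k <= 1) {
    abort("`k` must be a single number greater than 1.")
  }
  f <- log(k) / log(estimate$base)
  out <- estimate
  out$logrr <- estimate$logrr * f
  out$se <- estimate$se * f
  out$base <- k
  out
}

#' Odds-to-risk worked example
#'
#' A k-fold increase in *odds* expressed on the risk scale: a trebling in odds
#' takes a genetic risk of 10% (odds 1/9) to 25% (odds 1/3), and 25% to 50%.
#'
#' @param risk Baseline risk strictly inside (0, 1).
#' @param k Odds multiplier.
#' @return The new risk fraction.
#' @export
odds_risk_example <- function(risk, k) {
  if (any(risk <= 0 | risk >= 1)) {
    abort("`risk` must lie strictly between 0 and 1.")
  }
  odds <- risk / (1 - risk)
  k * odds / (1 + k * odds)
}
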