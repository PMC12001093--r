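new_assoc_estimate <- function(beta, se, n, n_events, scale, type,
                               exposure, loglik = NA_real_,
                               exposure_sd = NA_real_, ph_p = NA_real_) {
  structure(
    list(beta = beta, se = se, z = beta / se, n = n, n_events = n_events,
         scale = scale, type = type, exposure = exposure, loglik = loglik,
         exposure_sd = exposure_sd, ph_p = ph_p),
    class = "assoc_estimate"
  )
}

#' @export
print.assoc_estimate <- function(x, ...) {
  cat(sprintf("<assoc_estimate:%s> %s: beta %.4f (se %.4f), %s = %.4g, scale %s\n",
              x$type, x$exposure, x$beta, x$se,
              if (x$type == "cox") "HR" else "OR", exp(x$beta), x$scale))
  cat(sprintf("  n = %d, events/cases = %d\n", x$n, x$n_events))
  invisible(x)
}

#' @export
tidy.assoc_estimate <- function(x, ...) {
  tibble(term = x$exposure, estimate = x$beta, std.error = x$se,
         statistic = x$z, p.value = 2 * pnorm(-abs(x$z)))
}

#' @export
glance.assoc_estimate <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, scale = x$scale, type = x$type,
         logLik = x$loglik, ph_p = x$ph_p)
}

#' Rescale an association estimate to per-SD units
#'
#' Multiplies the per-unit log effect and its SE by the exposure SD, the
#' display convention for score-disease odds ratios.
#'
#' @param est An `assoc_estimate` fitted on the raw exposure scale.
#' @param exposure_sd SD to use; defaults to the SD recorded at fit time.
#' @return A new `assoc_estimate` with scale tag `"per_sd"`.
#' @export
per_sd <- function(est, exposure_sd = NULL) {
  s <- exposure_sd %||% est$exposure_sd
  if (!is.finite(s) || s <= 0) abort("a positive exposure SD is required.")
  out <- est
  out$beta <- est$beta * s
  out$se <- est$se * s
  out$z <- out$beta / out$se
  out$scale <- "per_sd"
  out
}

#' Age-at-risk stratified Cox fit
#'
#' Partial-likelihood estimate on Lexis episodes, with time since entry as the
#' timescale, Efron tie handling, and strata typically age band x sex. Deaths
#' from other causes must already be coded as non-events (cause-specific
#' hazard). Strata containing no events are dropped (optionally with a
#' warning). A Schoenfeld-style proportionality diagnostic p-value is attached
#' but does not gate the fit.
#'
#' @param episodes Episode tibble from [lexis_expand()] with `tstart`,
#'   `tstop`, `event`.
#' @param exposure Name of the exposure column.
#' @param covariates Optional character vector of adjustment columns.
#' @param strata Character vector of stratification columns.
#' @param warn_empty Warn when zero-event strata are dropped.
#' @param ph_diagnostic Compute the Schoenfeld-style proportionality p-value
#'   (adds one `cox.zph` pass; disable in tight simulation loops).
#' @return An `assoc_estimate` (log hazard ratio per exposure unit).
#' @export
fit_stratified_cox <- function(episodes, exposure, covariates = NULL,
                               strata = c("age_band", "sex"),
                               warn_empty = FALSE, ph_diagnostic = TRUE) {
  assert_cols(episodes, c("tstart", "tstop", "event", exposure, covariates,
                          strata), "episodes")
  key <- interaction(episodes[strata], drop = TRUE)
  ev_by <- tapply(episodes$event, key, sum)
  dead_strata <- names(ev_by)[ev_by == 0]
  if (length(dead_strata) > 0) {
    if (warn_empty) {
      warn(sprintf("dropping %d stratum(-a) without events", length(dead_strata)))
    }
    episodes <- episodes[!(key %in% dead_strata), , drop = FALSE]
  }
  if (sum(episodes$event) == 0) abort("no events available for the Cox fit.")
  if (stats::sd(episodes[[exposure]]) == 0) {
    abort("degenerate design: the exposure is constant, beta is undefined.")
  }
  rhs <- paste(c(exposure, covariates,
                 sprintf("strata(%s)", paste(strata, collapse = ", "))),
               collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(tstart, tstop, event) ~", rhs))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = episodes, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) {
      if (grepl("Ran out of iterations", conditionMessage(w))) {
        abort(sprintf("Cox fit did not converge: %s", conditionMessage(w)))
      }
      # "Loglik converged before variable" on a sparse adjustment level is
      # benign for the exposure estimate; muffle it
      invokeRestart("muffleWarning")
    }
  )
  cf <- summary(fit)$coefficients
  ph_p <- NA_real_
  if (ph_diagnostic) {
    ph_p <- tryCatch(
      {
        z <- survival::cox.zph(fit)
        unname(z$table["GLOBAL", "p"])
      },
      error = function(e) NA_real_
    )
  }
  new_assoc_estimate(
    beta = cf[exposure, "coef"], se = cf[exposure, "se(coef)"],
    n = length(unique(episodes$id %||% seq_len(nrow(episodes)))),
    n_events = sum(episodes$event),
    scale = "per_unit", type = "cox", exposure = exposure,
    loglik = fit$loglik[2],
    exposure_sd = stats::sd(episodes[[exposure]]),
    ph_p = ph_p
  )
}

#' Logistic association fit
#'
#' Maximum-likelihood logistic regression of a binary outcome on an exposure
#' with optional covariate adjustment. Complete separation is flagged and the
#' estimate withheld.
#'
#' @param data Tibble.
#' @param outcome Name of the binary outcome column (logical or 0/1).
#' @param exposure Name of the exposure column.
#' @param covariates Optional adjustment column names.
#' @return An `assoc_estimate` (log odds ratio per exposure unit) carrying
#'   the model log-likelihood for pseudo-R2 computation.
#' @export
fit_logistic <- function(data, outcome, exposure, covariates = NULL) {
  assert_cols(data, c(outcome, exposure, covariates), "data")
  y <- as.numeric(data[[outcome]])
  if (length(unique(y[!is.na(y)])) < 2) {
    abort("both outcome classes must be present.")
  }
  rhs <- paste(c(exposure, covariates), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- stats::glm(fml, data = data, family = stats::binomial())
  cf <- summary(fit)$coefficients
  beta <- cf[exposure, "Estimate"]
  if (fit$boundary || abs(beta) > 15 || cf[exposure, "Std. Error"] > 100) {
    abort("apparent separation in the logistic fit; estimate withheld.")
  }
  new_assoc_estimate(
    beta = beta, se = cf[exposure, "Std. Error"],
    n = stats::nobs(fit), n_events = sum(y == 1, na.rm = TRUE),
    scale = "per_unit", type = "logistic", exposure = exposure,
    loglik = as.numeric(stats::logLik(fit)),
    exposure_sd = stats::sd(data[[exposure]], na.rm = TRUE)
  )
}

#' Nagelkerke pseudo-R-squared
#'
#' `R2 = [1 - (L0/L1)^(2/n)] / [1 - L0^(2/n)]` for nested binary-outcome
#' models on the same data; bounded in `[0, 1]`.
#'
#' @param model,null Fitted model and its null (intercept-only or reduced)
#'   counterpart: `assoc_estimate` objects, `glm` fits, or lists with
#'   `loglik` and `n`.
#' @return The pseudo-R2 fraction.
#' @export
nagelkerke_r2 <- function(model, null) {
  get_ll <- function(x) {
    if (inherits(x, "assoc_estimate")) return(list(ll = x$loglik, n = x$n))
    if (inherits(x, "glm")) {
      return(list(ll = as.numeric(stats::logLik(x)), n = stats::nobs(x)))
    }
    list(ll = x$loglik, n = x$n)
  }
  m <- get_ll(model); n0 <- get_ll(null)
  if (m$n != n0$n) abort("models must be fitted to the same data.")
  if (m$ll < n0$ll - 1e-8) {
    abort("numerical error: fitted likelihood below the null likelihood.")
  }
  n <- m$n
  cs <- 1 - exp(2 * (n0$ll - m$ll) / n)
  maxr2 <- 1 - exp(2 * n0$ll / n)
  cs / maxr2
}

#' Per-SNP logistic scan
#'
#' Per-allele logistic associations of each SNP with the binary outcome,
#' adjusted for the given covariates; the summary-statistic outcome side of
#' the two-sample sensitivity suite, and the diagnostic for agreement with an
#' external weight file. Missing dosages are mean-imputed per SNP;
#' monomorphic SNPs are skipped with a reason.
#'
#' @param dosages Individuals x SNPs matrix (or [simulate_genotypes()] result).
#' @param outcome Binary vector (length = rows of `dosages`).
#' @param covariates Optional numeric matrix/data frame of adjustment columns.
#' @param weights Optional external weight tibble (`rsid`, `weight`); when
#'   given, the correlation between scan estimates and weights is attached as
#'   attribute `weight_correlation`.
#' @return Tibble: `rsid`, `beta`, `se`, `n_cases`, `status`.
#' @export
per_allele_scan <- function(dosages, outcome, covariates = NULL,
                            weights = NULL) {
  if (inherits(dosages, "sim_genotypes")) dosages <- dosages$dosages
  y <- as.numeric(outcome)
  stopifnot(length(y) == nrow(dosages))
  z <- if (is.null(covariates)) NULL else as.matrix(covariates)
  m <- ncol(dosages)
  beta <- se <- rep(NA_real_, m)
  status <- rep("ok", m)
  for (j in seq_len(m)) {
    x <- dosages[, j]
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    if (stats::sd(x) == 0) {
      status[j] <- "monomorphic"
      next
    }
    xmat <- cbind(`(Intercept)` = 1, snp = x, z)
    fit <- suppressWarnings(
      stats::glm.fit(xmat, y, family = stats::binomial())
    )
    vc <- tryCatch(chol2inv(qr.R(fit$qr)), error = function(e) NULL)
    if (is.null(vc)) {
      status[j] <- "fit_failed"
      next
    }
    beta[j] <- fit$coefficients["snp"]
    se[j] <- sqrt(diag(vc))[2]
  }
  out <- tibble(rsid = colnames(dosages) %||% as.character(seq_len(m)),
                beta = beta, se = se,
                n_cases = sum(y == 1), status = status)
  if (!is.null(weights)) {
    mtch <- match(out$rsid, weights$rsid)
    ok <- !is.na(mtch) & out$status == "ok"
    attr(out, "weight_correlation") <-
      stats::cor(out$beta[ok], weights$weight[mtch[ok]])
  }
  out
}
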