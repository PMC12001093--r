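#' Cause groups analysed by default
#' @return Character vector of cause-group labels (plus the `all_cause` and
#'   aggregate `vascular` endpoints).
#' @export
default_causes <- function() {
  c("all_cause", "vascular", "cardiac", "stroke", "infection", "renal",
    "cancer", "cirrhosis", "copd", "acute_diabetic_crisis")
}

expand_cause <- function(cause) {
  switch(cause,
    all_cause = NULL,  # NULL means every death
    vascular = c("cardiac", "stroke", "vascular_other"),
    cause
  )
}

#' Assemble the per-individual analysis table
#'
#' Joins classified phenotypes, re-attributed follow-up and a genetic risk
#' score into one row per individual, adding the combined T2D indicator
#' (previously diagnosed or undiagnosed).
#'
#' @param phenotypes Participant tibble ([classify_diabetes()] is applied if
#'   its columns are absent).
#' @param followup Follow-up tibble ([reattribute_cause()] is applied if
#'   `cause_group` is absent).
#' @param grs Optional `grs_result`; its `score`/`score_std` are joined.
#' @return One-row-per-individual analysis tibble.
#' @export
mr_input <- function(phenotypes, followup, grs = NULL) {
  if (!"diabetes_class" %in% names(phenotypes)) {
    phenotypes <- classify_diabetes(phenotypes)
  }
  if (!"cause_group" %in% names(followup)) {
    followup <- reattribute_cause(followup)
  }
  out <- dplyr::inner_join(phenotypes, followup, by = "id")
  if (!is.null(grs)) {
    out <- dplyr::inner_join(out, as_tibble(grs)[c("id", "score", "score_std")],
                             by = "id")
  }
  out$t2d <- !is.na(out$diabetes_class) &
    out$diabetes_class %in% c("previously_diagnosed", "undiagnosed")
  out
}

cause_events <- function(episodes, cause) {
  members <- expand_cause(cause)
  if (is.null(members)) episodes$event
  else episodes$event & !is.na(episodes$cause_group) &
    episodes$cause_group %in% members
}

new_mr_results <- function(df, denominator = NULL) {
  class(df) <- c("mr_results", class(df))
  attr(df, "denominator") <- denominator
  df
}

#' @export
tidy.mr_results <- function(x, ...) as_tibble(x)

#' @export
autoplot.mr_results <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::filter(is.finite(.data$rr)) |>
    mutate(label = factor(.data$cause, levels = rev(unique(.data$cause))))
  ggplot(df, aes(x = .data$rr, y = .data$label)) +
    geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    geom_point(shape = 15, size = 2.5) +
    geom_errorbarh(aes(xmin = .data$conf.low, xmax = .data$conf.high),
                   height = 0.15) +
    scale_x_log10() +
    labs(x = "rate ratio (95% CI)", y = NULL) +
    theme_minimal()
}

#' One-sample Mendelian randomisation over cause-specific mortality
#'
#' For each cause group: an age-band x sex stratified, PC-adjusted Cox fit of
#' the genetic score on cause-specific mortality forms the numerator; a
#' logistic fit of the score on T2D status (adjusted for age, sex and the
#' PCs) forms the common denominator; their ratio is rescaled so estimates
#' refer to a `k`-fold (default trebling) increase in genetically-predicted
#' odds of T2D.
#'
#' @param data Analysis tibble from [mr_input()] with `score`, `t2d`, `age`,
#'   `sex`, PCs, `entry_age`, `exit_age`, `died`, `cause_group`.
#' @param causes Cause groups to analyse (see [default_causes()]).
#' @param k Reporting base for predicted odds (default 3, a trebling).
#' @param se_method Passed to [wald_ratio()].
#' @param breaks Age grid for [lexis_expand()].
#' @param score Score column used as the instrument.
#' @param pcs Principal-component adjustment columns (those present are used).
#' @param ph_diagnostic Attach Schoenfeld-style proportionality p-values
#'   (disable in tight simulation loops).
#' @return An `mr_results` tibble: one row per cause with `logrr`, `se`,
#'   `rr`, CI bounds, `n_events`, `status`; the denominator fit is attached
#'   as an attribute.
#' @export
run_one_sample_mr <- function(data,
                              causes = default_causes(),
                              k = 3,
                              se_method = "simple",
                              breaks = seq(35, 75, 5),
                              score = "score",
                              pcs = paste0("pc", 1:7),
                              ph_diagnostic = TRUE) {
  pcs <- intersect(pcs, names(data))
  assert_cols(data, c(score, "t2d", "age", "sex", "entry_age", "exit_age",
                      "died", "cause_group"), "analysis data")
  if (stats::sd(data[[score]]) == 0) {
    abort("weak instrument: the genetic score is constant (zero weights?).")
  }
  denom <- fit_logistic(data, "t2d", score, c("age", "sex", pcs))

  keep <- c("id", score, "sex", pcs, "entry_age", "exit_age", "died",
            "cause_group")
  episodes <- lexis_expand(data[intersect(keep, names(data))], breaks)

  rows <- purrr::map_dfr(causes, function(cz) {
    ep <- episodes
    ep$event <- cause_events(ep, cz)
    n_ev <- sum(ep$event)
    if (n_ev == 0) {
      return(tibble(cause = cz, logrr = NA_real_, se = NA_real_,
                    rr = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
                    base = k, n_events = 0L, status = "insufficient_events"))
    }
    num <- fit_stratified_cox(ep, score, covariates = pcs,
                              strata = c("age_band", "sex"),
                              ph_diagnostic = ph_diagnostic)
    est <- rescale_base(wald_ratio(num, denom, se_method = se_method), k)
    td <- tidy(est)
    tibble(cause = cz, logrr = td$logrr, se = td$se, rr = td$rr,
           conf.low = td$conf.low, conf.high = td$conf.high, base = k,
           n_events = as.integer(n_ev),
           status = if (td$weak_instrument) "weak_instrument" else "ok")
  })
  new_mr_results(rows, denominator = denom)
}

#' Subgroup Mendelian randomisation
#'
#' Stratum-specific numerator Cox fits are combined with the *overall*
#' score-T2D denominator (subgroup-specific denominators would be unreliable
#' through larger random error), and between-stratum heterogeneity is
#' summarised by Cochran's Q on the stratum estimates.
#'
#' @inheritParams run_one_sample_mr
#' @param subgroup Name of a categorical column to stratify on.
#' @param cause Single cause group to analyse.
#' @return An `mr_results` tibble with one row per stratum and attributes
#'   `het_q`, `het_df`, `het_p`.
#' @export
subgroup_mr <- function(data, subgroup, cause = "all_cause", k = 3,
                        se_method = "simple", breaks = seq(35, 75, 5),
                        score = "score", pcs = paste0("pc", 1:7)) {
  pcs <- intersect(pcs, names(data))
  denom <- fit_logistic(data, "t2d", score, c("age", "sex", pcs))
  levels <- unique(as.character(data[[subgroup]]))
  rows <- purrr::map_dfr(levels, function(lv) {
    sub <- data[as.character(data[[subgroup]]) == lv, , drop = FALSE]
    keep <- c("id", score, "sex", pcs, "entry_age", "exit_age", "died",
              "cause_group")
    ep <- lexis_expand(sub[intersect(keep, names(sub))], breaks)
    ep$event <- cause_events(ep, cause)
    if (sum(ep$event) == 0) {
      return(tibble(stratum = lv, cause = cause, logrr = NA_real_,
                    se = NA_real_, rr = NA_real_, conf.low = NA_real_,
                    conf.high = NA_real_, base = k, n_events = 0L,
                    status = "no_events_dropped"))
    }
    num <- fit_stratified_cox(ep, score, covariates = pcs,
                              strata = c("age_band", "sex"))
    est <- rescale_base(wald_ratio(num, denom, se_method = se_method), k)
    td <- tidy(est)
    tibble(stratum = lv, cause = cause, logrr = td$logrr, se = td$se,
           rr = td$rr, conf.low = td$conf.low, conf.high = td$conf.high,
           base = k, n_events = as.integer(sum(ep$event)), status = "ok")
  })
  ok <- rows$status == "ok"
  out <- new_mr_results(rows, denominator = denom)
  if (sum(ok) >= 2) {
    w <- 1 / rows$se[ok]^2
    bbar <- sum(w * rows$logrr[ok]) / sum(w)
    q <- sum(w * (rows$logrr[ok] - bbar)^2)
    attr(out, "het_q") <- q
    attr(out, "het_df") <- sum(ok) - 1
    attr(out, "het_p") <- stats::pchisq(q, sum(ok) - 1, lower.tail = FALSE)
  } else {
    attr(out, "het_q") <- 0
    attr(out, "het_df") <- 0L
    attr(out, "het_p") <- NA_real_
  }
  out
}

#' Pathway-specific Mendelian randomisation
#'
#' Each pathway score is analysed as an instrument in its own right: its own
#' logistic score-T2D denominator, its own stratified Cox numerator, and
#' base-`k` rescaling, with SNP counts and small-instrument flags attached.
#' Cross-pathway heterogeneity (Cochran's Q) is reported to surface pathways
#' whose mortality association departs from the rest.
#'
#' @inheritParams run_one_sample_mr
#' @param pscores Long pathway score tibble from [pathway_scores()].
#' @param cause Single cause group to analyse.
#' @return An `mr_results` tibble with one row per pathway and heterogeneity
#'   attributes as in [subgroup_mr()].
#' @export
pathway_mr <- function(data, pscores, cause = "all_cause", k = 3,
                       se_method = "simple", breaks = seq(35, 75, 5),
                       pcs = paste0("pc", 1:7)) {
  pcs <- intersect(pcs, names(data))
  rows <- purrr::map_dfr(split(pscores, pscores$pathway), function(ps) {
    if (nrow(ps) == 0) return(NULL)
    sub <- dplyr::inner_join(
      dplyr::select(data, -dplyr::any_of(c("score", "score_std"))),
      ps[c("id", "score")], by = "id")
    status <- "ok"
    est <- tryCatch({
      denom <- fit_logistic(sub, "t2d", "score", c("age", "sex", pcs))
      keep <- c("id", "score", "sex", pcs, "entry_age", "exit_age", "died",
                "cause_group")
      ep <- lexis_expand(sub[intersect(keep, names(sub))], breaks)
      ep$event <- cause_events(ep, cause)
      num <- fit_stratified_cox(ep, "score", covariates = pcs,
                                strata = c("age_band", "sex"))
      withCallingHandlers(
        rescale_base(wald_ratio(num, denom, se_method = se_method), k),
        warning = function(w) {
          if (grepl("weak instrument", conditionMessage(w))) {
            status <<- "weak_instrument"
            invokeRestart("muffleWarning")
          }
        }
      )
    }, error = function(e) NULL)
    if (is.null(est)) {
      return(tibble(pathway = ps$pathway[1], cause = cause, logrr = NA_real_,
                    se = NA_real_, rr = NA_real_, conf.low = NA_real_,
                    conf.high = NA_real_, base = k, n_events = NA_integer_,
                    n_snps = ps$n_snps[1],
                    small_instrument = ps$small_instrument[1],
                    status = "failed"))
    }
    td <- tidy(est)
    tibble(pathway = ps$pathway[1], cause = cause, logrr = td$logrr,
           se = td$se, rr = td$rr, conf.low = td$conf.low,
           conf.high = td$conf.high, base = k, n_events = td$n_events,
           n_snps = ps$n_snps[1], small_instrument = ps$small_instrument[1],
           status = status)
  })
  ok <- rows$status %in% c("ok", "weak_instrument") & is.finite(rows$logrr)
  out <- new_mr_results(rows)
  if (sum(ok) >= 2) {
    w <- 1 / rows$se[ok]^2
    bbar <- sum(w * rows$logrr[ok]) / sum(w)
    q <- sum(w * (rows$logrr[ok] - bbar)^2)
    attr(out, "het_q") <- q
    attr(out, "het_df") <- sum(ok) - 1
    attr(out, "het_p") <- stats::pchisq(q, sum(ok) - 1, lower.tail = FALSE)
  }
  out
}

#' Observational T2D-mortality associations
#'
#' Cox rate ratios for diabetes status (previously diagnosed and undiagnosed,
#' separately and combined) per cause group, stratified by age band and sex
#' and adjusted for district, education, smoking, alcohol, and quarters of
#' height, weight, waist and hip circumference. Run on the observational
#' analysis population (prior-disease exclusions applied).
#'
#' @inheritParams run_one_sample_mr
#' @param diabetes `"combined"` for a single T2D indicator or `"separate"`
#'   for previously-diagnosed and undiagnosed contrasts.
#' @return An `mr_results`-style tibble with an `exposure` column; the scale
#'   is per T2D status, not per predicted odds.
#' @export
observational_mortality <- function(data,
                                    causes = default_causes(),
                                    diabetes = c("combined", "separate"),
                                    breaks = seq(35, 75, 5)) {
  diabetes <- match.arg(diabetes)
  adj <- intersect(c("district", "education", "smoking", "alcohol"),
                   names(data))
  for (v in intersect(c("height_cm", "weight_kg", "waist_cm", "hip_cm"),
                      names(data))) {
    qv <- paste0(v, "_q4")
    data[[qv]] <- factor(quantile_bins(data[[v]], 4))
    adj <- c(adj, qv)
  }
  exposures <- if (diabetes == "combined") {
    list(t2d = !is.na(data$diabetes_class) &
           data$diabetes_class %in% c("previously_diagnosed", "undiagnosed"))
  } else {
    list(previously_diagnosed = !is.na(data$diabetes_class) &
           data$diabetes_class == "previously_diagnosed",
         undiagnosed = !is.na(data$diabetes_class) &
           data$diabetes_class == "undiagnosed")
  }
  rows <- purrr::map_dfr(names(exposures), function(nm) {
    dd <- data
    dd$.expo <- as.numeric(exposures[[nm]])
    if (sum(dd$.expo) == 0) {
      return(tibble(exposure = nm, cause = causes, logrr = NA_real_,
                    se = NA_real_, rr = NA_real_, conf.low = NA_real_,
                    conf.high = NA_real_, n_events = 0L,
                    status = "empty_class_omitted"))
    }
    keep <- c("id", ".expo", "sex", adj, "entry_age", "exit_age", "died",
              "cause_group")
    ep_all <- lexis_expand(dd[intersect(keep, names(dd))], breaks)
    purrr::map_dfr(causes, function(cz) {
      ep <- ep_all
      ep$event <- cause_events(ep, cz)
      if (sum(ep$event) == 0) {
        return(tibble(exposure = nm, cause = cz, logrr = NA_real_,
                      se = NA_real_, rr = NA_real_, conf.low = NA_real_,
                      conf.high = NA_real_, n_events = 0L,
                      status = "insufficient_events"))
      }
      fit <- fit_stratified_cox(ep, ".expo", covariates = adj,
                                strata = c("age_band", "sex"))
      tibble(exposure = nm, cause = cz, logrr = fit$beta, se = fit$se,
             rr = exp(fit$beta),
             conf.low = exp(fit$beta - 1.96 * fit$se),
             conf.high = exp(fit$beta + 1.96 * fit$se),
             n_events = as.integer(fit$n_events), status = "ok")
    })
  })
  new_mr_results(rows)
}
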