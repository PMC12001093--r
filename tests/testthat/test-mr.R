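ae <- function(beta, se, n_events = 100L) {
  mrmort:::new_assoc_estimate(beta, se, n = 1000L, n_events = n_events,
                              scale = "per_unit", type = "cox",
                              exposure = "score")
}

test_that("the Wald ratio reproduces hand arithmetic and its SE methods", {
  num <- ae(0.15, 0.03)
  den <- ae(0.5, 1e-6)
  est <- wald_ratio(num, den, se_method = "simple")
  expect_equal(est$logrr, 0.30, tolerance = 1e-12)
  expect_equal(est$se, 0.06, tolerance = 1e-12)

  # delta converges to simple as the exposure SE vanishes
  d1 <- wald_ratio(num, ae(0.5, 1e-8), se_method = "delta")
  expect_equal(d1$se, 0.06, tolerance = 1e-6)
  # and exceeds it when the exposure is uncertain
  expect_warning(
    d2 <- wald_ratio(num, ae(0.5, 0.1), se_method = "delta"),
    "weak instrument")
  expect_gt(d2$se, 0.06)
  expect_equal(d2$se,
               sqrt(0.03^2 / 0.5^2 + 0.15^2 * 0.1^2 / 0.5^4),
               tolerance = 1e-12)

  # a null numerator gives a null ratio with a symmetric CI
  z <- wald_ratio(ae(0, 0.04), den)
  expect_equal(z$logrr, 0)
  td <- tidy(z)
  expect_equal(td$conf.low * td$conf.high, 1, tolerance = 1e-12)

  # the simple-method z-statistic equals the numerator z exactly
  expect_equal(est$logrr / est$se, num$beta / num$se, tolerance = 1e-12)

  expect_error(wald_ratio(num, ae(0, 0.01)), "undefined")
})

test_that("odds-base rescaling matches the published worked examples", {
  # ln 3 is the trebling multiplier, 1.10 to two decimals
  expect_equal(round(log(3), 2), 1.10)
  base_e <- mrmort:::new_mr_estimate(0.2546 / log(3), 0.01, base = exp(1))
  treb <- rescale_base(base_e, 3)
  expect_equal(treb$logrr / base_e$logrr, log(3), tolerance = 1e-12)

  # per-trebling RR 2.29 converts to per-doubling RR 1.69
  est229 <- mrmort:::new_mr_estimate(log(2.29), 0.05, base = 3)
  dbl <- rescale_base(est229, 2)
  expect_equal(round(exp(dbl$logrr), 2), 1.69)

  # identity and exact group action, for the CI endpoints too
  expect_equal(rescale_base(est229, 3)$logrr, est229$logrr)
  ab <- rescale_base(rescale_base(est229, 7), 2)
  expect_equal(ab$logrr, dbl$logrr, tolerance = 1e-12)
  expect_equal(ab$se, dbl$se, tolerance = 1e-12)
  expect_equal(tidy(ab)$conf.low, tidy(dbl)$conf.low, tolerance = 1e-12)

  expect_error(rescale_base(est229, 1), "greater than 1")
})

test_that("the odds-to-risk ladder climbs 10% -> 25% -> 50%", {
  expect_equal(odds_risk_example(0.10, 3), 0.25, tolerance = 1e-12)
  expect_equal(odds_risk_example(0.25, 3), 0.50, tolerance = 1e-12)
  expect_equal(odds_risk_example(0.50, 3), 0.75, tolerance = 1e-12)
  expect_equal(odds_risk_example(0.37, 1), 0.37)
  expect_error(odds_risk_example(0, 3), "strictly")
  expect_error(odds_risk_example(1, 3), "strictly")
})

test_that("the one-sample MR pipeline emits a row per cause with statuses", {
  dat <- shared_analysis_data()
  res <- suppressWarnings(
    run_one_sample_mr(dat, causes = c("all_cause", "renal", "copd"),
                      pcs = paste0("pc", 1:7)))
  expect_s3_class(res, "mr_results")
  expect_equal(res$cause, c("all_cause", "renal", "copd"))
  expect_equal(res$base, rep(3, 3))
  expect_true(all(res$status %in%
                    c("ok", "weak_instrument", "insufficient_events")))
  # the all-cause event count equals deaths inside the analysis window
  deaths_in_window <- sum(dat$died & dat$exit_age <= 75)
  expect_equal(res$n_events[1], deaths_in_window)
  # CI geometry is consistent with the point estimate and SE
  ok <- res$status != "insufficient_events"
  expect_equal(log(res$conf.low[ok]), res$logrr[ok] - 1.96 * res$se[ok],
               tolerance = 1e-12)

  # a constant score is rejected as a weak instrument
  dat0 <- dat
  dat0$score <- 1
  expect_error(run_one_sample_mr(dat0, causes = "all_cause"),
               "weak instrument")

  # a cause group nobody died from yields an insufficient-events row
  dat2 <- dat
  dat2$cause_group[dat2$cause_group == "copd"] <- "cancer"
  res2 <- suppressWarnings(run_one_sample_mr(dat2, causes = "copd"))
  expect_equal(res2$status, "insufficient_events")
  expect_equal(res2$n_events, 0L)
})

test_that("subgroup MR uses the overall denominator and detects homogeneity", {
  dat <- shared_analysis_data()
  # duplicate the cohort into two identical halves
  dat2 <- dplyr::bind_rows(
    dplyr::mutate(dat, half = "a"),
    dplyr::mutate(dat, half = "b", id = paste0(id, "_b"))
  )
  res <- suppressWarnings(subgroup_mr(dat2, "half", cause = "all_cause"))
  expect_equal(nrow(res), 2)
  expect_equal(res$logrr[1], res$logrr[2], tolerance = 1e-10)
  expect_lt(attr(res, "het_q"), 1e-10)

  # a single stratum reproduces the overall pipeline estimate
  dat$one <- "all"
  r1 <- suppressWarnings(subgroup_mr(dat, "one", cause = "all_cause"))
  r0 <- suppressWarnings(run_one_sample_mr(dat, causes = "all_cause"))
  expect_equal(r1$logrr, r0$logrr, tolerance = 1e-10)
  expect_equal(r1$se, r0$se, tolerance = 1e-10)
})

test_that("pathway MR scores each pathway as its own instrument", {
  co <- shared_cohort()
  dat <- shared_analysis_data()
  harm <- harmonize_weights(co$weights, panel_alleles(co$panel))
  ps <- pathway_scores(co$genotypes$dosages[dat$id, ], harm, min_snps = 5)
  res <- suppressWarnings(pathway_mr(dat, ps, cause = "all_cause"))
  expect_equal(sort(unique(res$pathway)), sort(unique(ps$pathway)))
  expect_true(all(res$n_snps[match(unique(ps$pathway), res$pathway)] ==
                    tapply(ps$n_snps, ps$pathway, unique)[unique(ps$pathway)]))
  expect_true(!is.null(attr(res, "het_q")))
})

test_that("observational contrasts run combined and separate diabetes classes", {
  dat <- shared_analysis_data()
  res <- observational_mortality(dat, causes = "all_cause",
                                 diabetes = "separate")
  expect_setequal(res$exposure, c("previously_diagnosed", "undiagnosed"))
  comb <- observational_mortality(dat, causes = "all_cause")
  expect_equal(comb$exposure, "t2d")
  expect_equal(comb$status, "ok")
  # diagnosed diabetes carries excess mortality under the default generator
  expect_gt(comb$rr, 1)
})

test_that("a pathway with a planted direct mortality effect stands out", {
  base_args <- list(n_individuals = 20000, n_snps = 200, n_pathways = 4,
                    n_pcs = 0, missing_rate = 0, seed = 777,
                    cause_hazards = list(all = c(rate = 5e-3,
                                                 log_rr = log(1.5))))
  run_pathways <- function(direct) {
    cfg <- do.call(sim_config, c(base_args,
                                 list(pathway_direct_effects = direct)))
    co <- simulate_cohort(cfg)
    harm <- harmonize_weights(co$weights, panel_alleles(co$panel))
    grs <- compute_grs(co$genotypes, harm)
    dat <- mr_input(co$phenotypes, co$followup, grs)
    dat <- apply_exclusions(dat, "genetic")$data
    ps <- pathway_scores(co$genotypes$dosages[dat$id, ], harm)
    suppressWarnings(pathway_mr(dat, ps, cause = "all_cause"))
  }

  # pathways generated exchangeably: no heterogeneity signal
  null_res <- run_pathways(list())
  expect_gt(attr(null_res, "het_p"), 0.01)

  # one pathway given an extra direct (non-T2D-mediated) mortality effect:
  # its estimate exceeds the others' and the heterogeneity statistic fires
  alt_res <- run_pathways(list(body_fat = 0.25))
  bf <- alt_res$logrr[alt_res$pathway == "body_fat"]
  expect_true(all(bf > alt_res$logrr[alt_res$pathway != "body_fat"]))
  expect_lt(attr(alt_res, "het_p"), 0.05)
})

test_that("planted between-stratum effect differences are detected", {
  mk <- function(b, seed, tag) {
    cfg <- sim_config(12000, 150, seed = seed, n_pcs = 0, missing_rate = 0,
                      weight_noise_ratio = 0,
                      cause_hazards = list(all = c(rate = 5e-3, log_rr = b)))
    co <- simulate_cohort(cfg)
    harm <- harmonize_weights(co$weights, panel_alleles(co$panel))
    grs <- compute_grs(co$genotypes, harm)
    dat <- mr_input(co$phenotypes, co$followup, grs)
    dat <- apply_exclusions(dat, "genetic")$data
    dat$id <- paste0(tag, dat$id)
    dat$stratum_var <- tag
    dat
  }
  both <- dplyr::bind_rows(mk(0, 5101, "null"), mk(log(6), 5102, "strong"))
  res <- suppressWarnings(subgroup_mr(both, "stratum_var",
                                      cause = "all_cause"))
  est <- setNames(res$logrr, res$stratum)
  expect_gt(est["strong"], est["null"])
  expect_lt(attr(res, "het_p"), 0.05)
})

test_that("the wider age windows admit older deaths", {
  dat <- shared_analysis_data()
  r75 <- suppressWarnings(run_one_sample_mr(dat, causes = "all_cause"))
  r85 <- suppressWarnings(run_one_sample_mr(dat, causes = "all_cause",
                                            breaks = seq(35, 85, 5)))
  expect_gt(r85$n_events, r75$n_events)
  expect_equal(r85$n_events[1], sum(dat$died & dat$exit_age <= 85))
})
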