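mk_record <- function(hba1c = 5.5, self_report = FALSE, meds = FALSE,
                      insulin = FALSE, diag_age = NA_real_) {
  tibble::tibble(hba1c = hba1c, self_report_diabetes = self_report,
                 diabetes_medication = meds, insulin = insulin,
                 diag_age = diag_age)
}

test_that("diabetes classification follows the stated precedence", {
  # self-report at age 30 on insulin: likely type 1, despite being diagnosed
  r <- classify_diabetes(mk_record(hba1c = 9, self_report = TRUE,
                                   insulin = TRUE, diag_age = 30))
  expect_equal(as.character(r$diabetes_class), "likely_t1d")

  # diagnosed at 40 on insulin: previously diagnosed T2D
  r <- classify_diabetes(mk_record(self_report = TRUE, insulin = TRUE,
                                   diag_age = 40))
  expect_equal(as.character(r$diabetes_class), "previously_diagnosed")

  # medication use alone counts as previously diagnosed
  r <- classify_diabetes(mk_record(meds = TRUE))
  expect_equal(as.character(r$diabetes_class), "previously_diagnosed")

  # the HbA1c threshold is inclusive at 6.5 and exclusive below it
  expect_equal(as.character(classify_diabetes(mk_record(6.5))$diabetes_class),
               "undiagnosed")
  expect_equal(as.character(classify_diabetes(mk_record(6.49))$diabetes_class),
               "none")

  # missing HbA1c without self-report is flagged, not classified
  r <- classify_diabetes(mk_record(hba1c = NA))
  expect_true(is.na(r$diabetes_class))
  expect_true(r$missing_data)
})

test_that("classification is total and exclusive on records passing the gate", {
  co <- shared_cohort()
  ph <- classify_diabetes(co$phenotypes)
  gate_ok <- !ph$missing_data
  expect_false(anyNA(ph$diabetes_class[gate_ok]))
  # the four classes are levels of one factor: mutually exclusive by type
  expect_setequal(levels(ph$diabetes_class),
                  c("none", "previously_diagnosed", "undiagnosed",
                    "likely_t1d"))
})

mk_death <- function(code, secondary = "") {
  tibble::tibble(died = TRUE, cause_icd10 = code,
                 secondary_causes = secondary)
}

test_that("cause re-attribution follows the acute-crisis rule and priorities", {
  # diabetes underlying cause with a renal secondary: re-attributed to renal
  expect_equal(reattribute_cause(mk_death("E11.9", "N18.9"))$cause_group,
               "renal")
  # acute crisis codes are accepted as diabetes deaths
  expect_equal(reattribute_cause(mk_death("E11.0"))$cause_group,
               "acute_diabetic_crisis")
  expect_equal(reattribute_cause(mk_death("E14.1"))$cause_group,
               "acute_diabetic_crisis")
  # non-diabetes codes pass through the group table
  expect_equal(reattribute_cause(mk_death("I21.9"))$cause_group, "cardiac")
  expect_equal(reattribute_cause(mk_death("I63.4"))$cause_group, "stroke")
  expect_equal(reattribute_cause(mk_death("C50.9"))$cause_group, "cancer")
  expect_equal(reattribute_cause(mk_death("K74.6"))$cause_group, "cirrhosis")
  expect_equal(reattribute_cause(mk_death("N39.0"))$cause_group, "infection")
  # renal outranks cardiac in the default priority list
  expect_equal(reattribute_cause(mk_death("E11.9", "I21.9;N18.9"))$cause_group,
               "renal")
  # a lower-priority mappable secondary is still used when no listed one is
  expect_equal(reattribute_cause(mk_death("E11.9", "C61"))$cause_group,
               "cancer")
  # nothing mappable: uncertain
  expect_equal(reattribute_cause(mk_death("E11.9"))$cause_group, "uncertain")
  expect_equal(reattribute_cause(mk_death("ZZZ"))$cause_group, "uncertain")
  # survivors carry no cause group
  alive <- tibble::tibble(died = FALSE, cause_icd10 = NA_character_,
                          secondary_causes = "")
  expect_true(is.na(reattribute_cause(alive)$cause_group))
})

test_that("re-attribution never inflates the uncertain count over pass-through", {
  co <- shared_cohort()
  fu <- reattribute_cause(co$followup)
  # pass-through = group table only, with every diabetes code left unmapped
  pass <- mrmort:::icd_to_group(fu$cause_icd10[fu$died])
  pass_uncertain <- sum(pass %in% c("uncertain", "diabetes"))
  expect_lte(sum(fu$cause_group[fu$died] == "uncertain"), pass_uncertain)
  # cause-group death counts sum to total deaths
  expect_equal(sum(table(fu$cause_group)), sum(fu$died))
})

test_that("the exclusion cascade matches a brute-force set computation", {
  co <- shared_cohort()
  dat <- mr_input(co$phenotypes, co$followup)
  # plant violations of each kind
  dat$age[1:5] <- 80
  dat$height_cm[6:10] <- 95
  dat$hba1c[11:12] <- NA
  dat$missing_data[11:12] <- TRUE
  dat$duplicate[13:15] <- TRUE
  dat$genetic_missing[16:20] <- TRUE
  res <- apply_exclusions(dat, "genetic")

  # brute-force first-match set logic
  r1 <- dat$age >= 75
  r2 <- !is.na(dat$diabetes_class) & dat$diabetes_class == "likely_t1d"
  win <- list(height_cm = c(100, 220), weight_kg = c(20, 250),
              waist_cm = c(40, 200), hip_cm = c(40, 200), hba1c = c(3, 20))
  r3 <- dat$missing_data
  for (v in names(win)) {
    r3 <- r3 | is.na(dat[[v]]) | dat[[v]] < win[[v]][1] | dat[[v]] > win[[v]][2]
  }
  r4 <- dat$died & !is.na(dat$cause_group) & dat$cause_group == "uncertain"
  r5 <- dat$duplicate
  r6 <- dat$genetic_missing
  excluded <- r1 | r2 | r3 | r4 | r5 | r6
  expect_setequal(res$data$id, dat$id[!excluded])

  led <- res$ledger
  expect_equal(sum(led$n_excluded), sum(excluded))
  expect_equal(led$n_excluded[led$reason == "aged_75_or_older"], 5)
  expect_equal(led$n_excluded[led$reason == "duplicate_record"], 3)
  expect_equal(led$n_excluded[led$reason == "missing_genetic_data"], 5)
  # first-match: the planted height outliers were not already taken
  expect_gte(led$n_excluded[led$reason == "missing_or_extreme_data"], 7)
})

test_that("ledger arithmetic conserves counts and rejects overdrafts", {
  led <- exclusion_ledger(100, c(a = 10, b = 5))
  expect_equal(ledger_remaining(led), 85)
  expect_equal(attr(led, "initial") - sum(led$n_excluded),
               ledger_remaining(led))
  expect_error(exclusion_ledger(10, c(a = 11)), "exceed")

  empty <- apply_exclusions(tibble::tibble(), "genetic")
  expect_equal(nrow(empty$data), 0)
  expect_equal(ledger_remaining(empty$ledger), 0)
})

test_that("observational exclusions additionally remove prior disease", {
  co <- shared_cohort()
  dat <- mr_input(co$phenotypes, co$followup)
  res <- apply_exclusions(dat, "observational")
  prior <- dat$prior_ihd | dat$prior_stroke | dat$prior_ckd |
    dat$prior_cirrhosis | dat$prior_cancer | dat$prior_emphysema
  expect_false(any(res$data$prior_ihd | res$data$prior_cancer))
  expect_equal(
    res$ledger$n_excluded[res$ledger$reason == "prior_chronic_disease"],
    sum(prior & !(dat$age >= 75) &
          !(dat$diabetes_class == "likely_t1d" & !is.na(dat$diabetes_class)) &
          !(dat$died & dat$cause_group == "uncertain" &
              !is.na(dat$cause_group))))
})

test_that("baseline tables match independent tabulation", {
  co <- shared_cohort()
  ph <- co$phenotypes
  tab <- baseline_table(ph, by = "sex", vars = c("age", "bmi", "smoking"))
  overall_age <- tab[tab$variable == "age" & tab$group == "overall", ]
  expect_equal(overall_age$mean, mean(ph$age))
  expect_equal(overall_age$sd, sd(ph$age))
  women_bmi <- tab[tab$variable == "bmi" & tab$group == "women", ]
  expect_equal(women_bmi$mean, mean(ph$bmi[ph$sex == "women"]))
  smk <- tab[tab$variable == "smoking" & tab$group == "men" &
               tab$level == "never", ]
  expect_equal(smk$n, sum(ph$smoking[ph$sex == "men"] == "never"))
  expect_equal(smk$pct, 100 * smk$n / sum(ph$sex == "men"))

  single <- baseline_table(ph[1, ], by = "sex", vars = "age")
  expect_equal(single$sd[single$group == "overall"], 0)
})

test_that("confounder balance flags self-association and nothing else", {
  co <- shared_cohort()
  harm <- harmonize_weights(co$weights, panel_alleles(co$panel))
  g <- compute_grs(co$genotypes, harm)
  bins <- quantile_bins(g$score, 5)
  dat <- co$phenotypes
  dat$self <- g$score
  dat$constant <- 1
  bal <- confounder_balance(dat, bins,
                            c("height_cm", "bmi", "self", "constant"))
  tr <- tidy(bal)
  # the score itself shows a monotone trend across fifths
  self_means <- bal$bin_means$mean[bal$bin_means$covariate == "self"]
  expect_true(all(diff(self_means) > 0))
  expect_gt(abs(tr$z[tr$covariate == "self"]), 10)
  # a constant covariate has exactly zero slope
  expect_equal(tr$slope[tr$covariate == "constant"], 0)
  # genuinely independent covariates show no strong trend
  expect_lt(abs(tr$z[tr$covariate == "height_cm"]), 4)
})
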