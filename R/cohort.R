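#' Classify diabetes status at recruitment
#'
#' Likely type 1 diabetes takes precedence (self-reported diagnosis before age
#' 35 and insulin use at recruitment); then previously diagnosed (self-reported
#' doctor diagnosis or diabetes medication use); then undiagnosed (no previous
#' diagnosis but HbA1c >= 6.5%); otherwise none. Records with no self-report
#' and missing HbA1c cannot be classified and are flagged for the
#' missing-data exclusion instead.
#'
#' @param data Participant tibble with `hba1c`, `self_report_diabetes`,
#'   `diabetes_medication`, `insulin`, `diag_age`.
#' @param threshold HbA1c diagnostic threshold (%, default 6.5).
#' @return `data` with `diabetes_class` (factor: none, previously_diagnosed,
#'   undiagnosed, likely_t1d; `NA` when unclassifiable) and a logical
#'   `missing_data` flag.
#' @export
classify_diabetes <- function(data, threshold = 6.5) {
  assert_cols(data, c("hba1c", "self_report_diabetes", "diabetes_medication",
                      "insulin", "diag_age"), "participant data")
  prev <- data$self_report_diabetes | data$diabetes_medication
  t1d <- data$self_report_diabetes & data$insulin &
    !is.na(data$diag_age) & data$diag_age < 35
  missing_gate <- !prev & is.na(data$hba1c)
  cls <- rep(NA_character_, nrow(data))
  cls[!prev & !missing_gate & data$hba1c >= threshold] <- "undiagnosed"
  cls[!prev & !missing_gate & data$hba1c < threshold] <- "none"
  cls[prev] <- "previously_diagnosed"
  cls[t1d] <- "likely_t1d"
  data$diabetes_class <- factor(cls, levels = c("none", "previously_diagnosed",
                                                "undiagnosed", "likely_t1d"))
  data$missing_data <- missing_gate
  data
}

#' Default ICD-10 to cause-group mapping
#'
#' Prefix-range table following WHO chapter conventions. This default is a
#' plain editable stand-in, not a canonical endpoint definition: studies ship
#' their own appendix code lists, and this table exists so the pipeline's
#' cause grouping is explicit and configurable.
#'
#' @return Tibble with `letter`, `lo`, `hi` (inclusive 2-digit range) and
#'   `group`; earlier rows win.
#' @export
default_cause_map <- function() {
  tribble_row <- function(letter, lo, hi, group) {
    tibble(letter = letter, lo = lo, hi = hi, group = group)
  }
  dplyr::bind_rows(
    tribble_row("A", 0, 99, "infection"),
    tribble_row("B", 0, 99, "infection"),
    tribble_row("C", 0, 99, "cancer"),
    tribble_row("D", 0, 48, "cancer"),
    tribble_row("D", 49, 99, "other_medical"),
    tribble_row("I", 20, 25, "cardiac"),
    tribble_row("I", 60, 69, "stroke"),
    tribble_row("I", 0, 99, "vascular_other"),
    tribble_row("J", 9, 18, "infection"),
    tribble_row("J", 40, 47, "copd"),
    tribble_row("J", 0, 99, "other_medical"),
    tribble_row("K", 70, 70, "cirrhosis"),
    tribble_row("K", 74, 74, "cirrhosis"),
    tribble_row("K", 0, 99, "other_medical"),
    tribble_row("N", 0, 29, "renal"),
    tribble_row("N", 30, 39, "infection"),
    tribble_row("N", 40, 99, "other_medical"),
    tribble_row("R", 0, 99, "ill_defined"),
    tribble_row("V", 0, 99, "external"),
    tribble_row("W", 0, 99, "external"),
    tribble_row("X", 0, 99, "external"),
    tribble_row("Y", 0, 99, "external"),
    tribble_row("E", 0, 9, "other_medical"),
    tribble_row("E", 15, 99, "other_medical"),
    tribble_row("F", 0, 99, "other_medical"),
    tribble_row("G", 0, 99, "other_medical"),
    tribble_row("H", 0, 99, "other_medical"),
    tribble_row("L", 0, 99, "other_medical"),
    tribble_row("M", 0, 99, "other_medical"),
    tribble_row("O", 0, 99, "other_medical"),
    tribble_row("P", 0, 99, "other_medical"),
    tribble_row("Q", 0, 99, "other_medical")
  )
}

parse_icd <- function(code) {
  code <- toupper(gsub("\\s", "", code))
  letter <- substr(code, 1, 1)
  num <- suppressWarnings(as.integer(substr(code, 2, 3)))
  rest <- sub("^[A-Z][0-9]{2}\\.?", "", code)
  sub <- suppressWarnings(as.integer(substr(rest, 1, 1)))
  list(letter = letter, num = num, sub = sub)
}

# map a vector of ICD-10 codes to cause groups ("uncertain" when unmappable);
# diabetes codes (E10-E14) return "diabetes" for special handling upstream
icd_to_group <- function(codes, cause_map = default_cause_map()) {
  p <- parse_icd(codes)
  out <- rep("uncertain", length(codes))
  diab <- !is.na(p$num) & p$letter == "E" & p$num >= 10 & p$num <= 14
  out[diab] <- "diabetes"
  todo <- !diab & !is.na(p$num) & p$letter %in% unique(cause_map$letter)
  for (i in seq_len(nrow(cause_map))) {
    hit <- todo & p$letter == cause_map$letter[i] &
      p$num >= cause_map$lo[i] & p$num <= cause_map$hi[i]
    out[hit] <- cause_map$group[i]
    todo <- todo & !hit
  }
  out
}

#' Re-attribute underlying causes of death
#'
#' Deaths certified with diabetes as the raw underlying cause are accepted as
#' diabetes deaths only when the code marks an acute crisis (4th digit 0 or 1,
#' i.e. coma or ketoacidosis); other diabetes-coded deaths are re-attributed
#' to the highest-priority mappable secondary cause on the certificate
#' (default priority renal > cardiac > stroke > infection > any other
#' mappable cause). Non-diabetes codes map directly through the ICD-10 group
#' table. Deaths with no mappable cause become "uncertain" and are excluded
#' downstream.
#'
#' @param followup Follow-up tibble with `died`, `cause_icd10`,
#'   `secondary_causes` (semicolon-separated codes, may be empty).
#' @param cause_map See [default_cause_map()].
#' @param priority Character vector of cause groups tried in order during
#'   re-attribution.
#' @return `followup` with a `cause_group` column (`NA` for survivors).
#' @export
reattribute_cause <- function(followup,
                              cause_map = default_cause_map(),
                              priority = c("renal", "cardiac", "stroke",
                                           "infection")) {
  assert_cols(followup, c("died", "cause_icd10", "secondary_causes"),
              "follow-up data")
  n <- nrow(followup)
  group <- rep(NA_character_, n)
  dead <- which(followup$died)
  if (length(dead) > 0) {
    raw <- followup$cause_icd10[dead]
    g <- icd_to_group(raw, cause_map)
    p <- parse_icd(raw)
    is_diab <- g == "diabetes"
    acute <- is_diab & !is.na(p$sub) & p$sub <= 1
    g[acute] <- "acute_diabetic_crisis"
    for (j in which(is_diab & !acute)) {
      secs <- strsplit(followup$secondary_causes[dead[j]], ";")[[1]]
      secs <- secs[nzchar(trimws(secs))]
      gg <- if (length(secs)) icd_to_group(trimws(secs), cause_map) else character(0)
      gg <- gg[!gg %in% c("uncertain", "diabetes")]
      pick <- intersect(priority, gg)
      g[j] <- if (length(pick)) pick[1] else if (length(gg)) gg[1] else "uncertain"
    }
    group[dead] <- g
  }
  followup$cause_group <- group
  followup
}

#' Build an exclusion ledger from category counts
#'
#' Plain bookkeeping: ordered (reason, count) pairs plus the implied
#' remainder, with the conservation identity `initial - sum(counts) =
#' remaining` enforced.
#'
#' @param initial Starting number of individuals.
#' @param counts Named numeric vector of exclusion counts, in order.
#' @return An `exclusion_ledger` tibble (`reason`, `n_excluded`) with
#'   attributes `initial` and `remaining`.
#' @export
exclusion_ledger <- function(initial, counts) {
  if (is.null(names(counts)) && length(counts) > 0) {
    abort("`counts` must be named by exclusion reason.")
  }
  remaining <- initial - sum(counts)
  if (remaining < 0) abort("exclusion counts exceed the initial count.")
  out <- tibble(reason = names(counts), n_excluded = as.numeric(counts))
  attr(out, "initial") <- initial
  attr(out, "remaining") <- remaining
  class(out) <- c("exclusion_ledger", class(out))
  out
}

#' Total remaining after an exclusion ledger
#' @param ledger An `exclusion_ledger`.
#' @return Number of individuals remaining.
#' @export
ledger_remaining <- function(ledger) attr(ledger, "remaining")

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat(sprintf("<exclusion_ledger> initial %s\n",
              format(attr(x, "initial"), big.mark = ",")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  - %-28s %s\n", x$reason[i],
                format(x$n_excluded[i], big.mark = ",")))
  }
  cat(sprintf("  remaining %s\n", format(attr(x, "remaining"), big.mark = ",")))
  invisible(x)
}

default_plausibility_windows <- function() {
  list(height_cm = c(100, 220), weight_kg = c(20, 250),
       waist_cm = c(40, 200), hip_cm = c(40, 200), hba1c = c(3, 20))
}

#' Apply the eligibility cascade
#'
#' Exclusions are applied in the stated order — age 75 or older at
#' recruitment, likely type 1 diabetes, missing or extreme exposure/covariate
#' data, uncertain cause of death, duplicate recruitment — followed by the
#' analysis-specific step: missing genetic data (genetic analyses) or
#' previously diagnosed chronic disease other than diabetes (observational
#' analyses). Each individual is counted once, under the first matching
#' reason.
#'
#' @param data Cohort tibble after [classify_diabetes()] and
#'   [reattribute_cause()] results have been joined (needs `age`,
#'   `diabetes_class`, `missing_data`, `died`, `cause_group`, `duplicate`,
#'   `genetic_missing`, and the `prior_*` flags for observational analyses).
#' @param analysis `"genetic"` or `"observational"`.
#' @param windows Named list of plausibility windows for covariates; values
#'   outside them count as extreme.
#' @return An `exclusion_result` list: `data` (remaining rows) and `ledger`.
#' @export
apply_exclusions <- function(data,
                             analysis = c("genetic", "observational"),
                             windows = default_plausibility_windows()) {
  analysis <- match.arg(analysis)
  if (nrow(data) == 0) {
    return(structure(list(data = data,
                          ledger = exclusion_ledger(0, numeric(0))),
                     class = "exclusion_result"))
  }
  assert_cols(data, c("age", "diabetes_class", "missing_data", "died",
                      "cause_group"), "cohort data")
  dup <- data$duplicate %||% rep(FALSE, nrow(data))
  gmiss <- data$genetic_missing %||% rep(FALSE, nrow(data))

  extreme <- rep(FALSE, nrow(data))
  for (v in names(windows)) {
    if (!v %in% names(data)) next
    x <- data[[v]]
    extreme <- extreme | is.na(x) | x < windows[[v]][1] | x > windows[[v]][2]
  }

  reasons <- list(
    aged_75_or_older = !is.na(data$age) & data$age >= 75,
    likely_t1d = !is.na(data$diabetes_class) & data$diabetes_class == "likely_t1d",
    missing_or_extreme_data = data$missing_data | extreme | is.na(data$age),
    uncertain_cause_of_death = data$died & !is.na(data$cause_group) &
      data$cause_group == "uncertain",
    duplicate_record = dup
  )
  if (analysis == "genetic") {
    reasons$missing_genetic_data <- gmiss
  } else {
    prior_cols <- grep("^prior_", names(data), value = TRUE)
    prior <- if (length(prior_cols)) {
      Reduce(`|`, lapply(prior_cols, function(cc) isTRUE_vec(data[[cc]])))
    } else rep(FALSE, nrow(data))
    reasons$prior_chronic_disease <- prior
  }

  taken <- rep(FALSE, nrow(data))
  counts <- numeric(0)
  for (nm in names(reasons)) {
    hit <- reasons[[nm]] & !taken
    counts[nm] <- sum(hit)
    taken <- taken | hit
  }
  structure(
    list(data = data[!taken, , drop = FALSE],
         ledger = exclusion_ledger(nrow(data), counts)),
    class = "exclusion_result"
  )
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' @export
print.exclusion_result <- function(x, ...) {
  print(x$ledger)
  invisible(x)
}
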