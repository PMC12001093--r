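#' Baseline characteristics table
#'
#' Mean (SD) for continuous variables and n (%) for categorical ones, overall
#' and within groups. A single-individual group reports an SD of 0.
#'
#' @param data Cohort tibble.
#' @param by Grouping column name (default `"sex"`).
#' @param vars Variables to summarise; defaults to all columns other than
#'   `id` and the grouping column.
#' @return A long tibble: `variable`, `level` (`NA` for continuous rows),
#'   `group` (including `"overall"`), `n`, `mean`, `sd`, `pct`.
#' @export
baseline_table <- function(data, by = "sex", vars = NULL) {
  if (nrow(data) == 0) abort("cohort is empty.")
  vars <- vars %||% setdiff(names(data), c("id", by))
  groups <- c("overall", as.character(unique(data[[by]])))
  purrr::map_dfr(vars, function(v) {
    x_all <- data[[v]]
    purrr::map_dfr(groups, function(g) {
      x <- if (g == "overall") x_all else x_all[data[[by]] == g]
      if (is.numeric(x)) {
        tibble(variable = v, level = NA_character_, group = g,
               n = sum(!is.na(x)),
               mean = mean(x, na.rm = TRUE),
               sd = if (sum(!is.na(x)) > 1) stats::sd(x, na.rm = TRUE) else 0,
               pct = NA_real_)
      } else {
        tab <- table(x)
        tibble(variable = v, level = names(tab), group = g,
               n = as.numeric(tab),
               mean = NA_real_, sd = NA_real_,
               pct = 100 * as.numeric(tab) / length(x[!is.na(x)]))
      }
    })
  })
}

#' Covariate balance across score bins
#'
#' Per-bin covariate means plus a linear trend of each covariate on the bin
#' mid-rank (bin index centred at zero), the usual check that a genetic score
#' is not associated with potential confounders.
#'
#' @param data Cohort tibble.
#' @param bins Integer bin assignment (e.g. from [quantile_bins()]).
#' @param covariates Covariate column names; non-numeric columns are used via
#'   their level indicators' numeric coding only if two-level, otherwise
#'   skipped.
#' @return A `confounder_balance` list: `bin_means` tibble and `trends`
#'   tibble (`covariate`, `slope`, `se`, `z`).
#' @export
confounder_balance <- function(data, bins, covariates) {
  stopifnot(length(bins) == nrow(data))
  k <- max(bins)
  mid <- bins - (k + 1) / 2
  res <- purrr::map(covariates, function(v) {
    x <- data[[v]]
    if (!is.numeric(x)) {
      lv <- unique(stats::na.omit(x))
      if (length(lv) != 2) return(NULL)
      x <- as.numeric(x == lv[2])
    }
    bm <- tibble(covariate = v, bin = seq_len(k)) |>
      mutate(mean = vapply(.data$bin, function(b) mean(x[bins == b], na.rm = TRUE),
                           numeric(1)))
    if (stats::sd(x, na.rm = TRUE) == 0) {
      tr <- tibble(covariate = v, slope = 0, se = NA_real_, z = NA_real_)
    } else {
      fit <- stats::lm(x ~ mid)
      cf <- summary(fit)$coefficients
      tr <- tibble(covariate = v, slope = cf["mid", 1], se = cf["mid", 2],
                   z = cf["mid", 1] / cf["mid", 2])
    }
    list(bin_means = bm, trends = tr)
  })
  res <- purrr::compact(res)
  structure(
    list(bin_means = purrr::map_dfr(res, "bin_means"),
         trends = purrr::map_dfr(res, "trends")),
    class = "confounder_balance"
  )
}

#' @export
tidy.confounder_balance <- function(x, ...) x$trends

#' @export
print.confounder_balance <- function(x, ...) {
  cat("<confounder_balance>\n")
  print(x$trends)
  invisible(x)
}

#' @export
autoplot.confounder_balance <- function(object, ...) {
  ggplot(object$bin_means, aes(x = .data$bin, y = .data$mean)) +
    geom_point() +
    geom_line() +
    facet_wrap(~covariate, scales = "free_y") +
    labs(x = "score bin", y = "covariate mean") +
    theme_minimal()
}
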