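#' Lexis expansion into age-at-risk bands
#'
#' Splits each individual's follow-up into 5-year age-band episodes so that
#' proportional-hazards fits on the time-since-entry timescale can be
#' stratified by attained age. Episodes cover the intersection of
#' `[entry, exit)` with the band grid; the death event is assigned to the band
#' containing the exit age; no person-time is contributed below the grid floor
#' or beyond its ceiling, and deaths beyond the ceiling are censored there.
#'
#' @param data Tibble with `entry_age`, `exit_age`, `died` (other columns are
#'   carried through).
#' @param breaks Age grid; default `seq(35, 75, 5)` gives bands
#'   `[35,40), ..., [70,75)` with analysis ceiling 75. Use
#'   `seq(75, 85, 5)` or `seq(35, 85, 5)` for the older windows.
#' @return Episode tibble with `age_band` (factor), `band_start`, `tstart`,
#'   `tstop` (time since entry, years) and `event`.
#' @export
lexis_expand <- function(data, breaks = seq(35, 75, 5)) {
  assert_cols(data, c("entry_age", "exit_age", "died"), "follow-up data")
  if (any(data$exit_age <= data$entry_age)) {
    abort("exit age must exceed entry age for every individual.")
  }
  nb <- length(breaks) - 1
  labels <- sprintf("[%g,%g)", breaks[-length(breaks)], breaks[-1])
  ceiling_age <- breaks[length(breaks)]
  pieces <- vector("list", nb)
  for (b in seq_len(nb)) {
    lo <- breaks[b]; hi <- breaks[b + 1]
    a0 <- pmax(data$entry_age, lo)
    a1 <- pmin(data$exit_age, hi)
    keep <- a1 > a0
    if (!any(keep)) next
    piece <- data[keep, , drop = FALSE]
    piece$age_band <- factor(labels[b], levels = labels)
    piece$band_start <- lo
    piece$tstart <- a0[keep] - piece$entry_age
    piece$tstop <- a1[keep] - piece$entry_age
    piece$event <- piece$died & piece$exit_age > lo &
      piece$exit_age <= hi & piece$exit_age <= ceiling_age
    pieces[[b]] <- piece
  }
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) > 0 && "id" %in% names(out)) {
    out <- dplyr::arrange(out, .data$id, .data$tstart)
  }
  out
}
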