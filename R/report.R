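#' Monthly surveillance report
#'
#' One row per calendar month of the reporting period: event counts and
#' classification mix (events assigned to months by onset), incidence per
#' 1000 patient-days (monthly patient-day denominators from the episode
#' set), and confirmation-delay mean/SD (events assigned by confirmation
#' month, since delay is a property of the confirmation workflow). Row
#' sums equal the pipeline totals for events with onset inside the period.
#'
#' @param events a classified event tibble (see [run_pipeline()]),
#'   optionally with `confirmation_ts` filled in.
#' @param episodes an episode tibble from [link_stays()] (denominators).
#' @param period `c(first_day, last_day)`, inclusive.
#' @return a tibble with columns `month`, `n_events`, one count column per
#'   classification, `patient_days`, `rate_per_1000_patient_days`,
#'   `n_confirmed`, `mean_delay_days`, `sd_delay_days`.
#' @export
monthly_report <- function(events, episodes, period) {
  period <- parse_date(period)
  if (length(period) != 2 || any(is.na(period)) || period[2] < period[1]) {
    abort_habsi("period must be c(first_day, last_day) with last >= first")
  }
  month_start <- seq(as.Date(format(period[1], "%Y-%m-01")),
                     as.Date(format(period[2], "%Y-%m-01")), by = "month")
  months <- format(month_start, "%Y-%m")
  month_end <- vapply(month_start, function(m) {
    as.character(seq(m, by = "month", length.out = 2)[2] - 1)
  }, character(1))

  ev <- events[!is.na(events$onset_ts) &
                 as.Date(fmt_ts(events$onset_ts)) >= period[1] &
                 as.Date(fmt_ts(events$onset_ts)) <= period[2], , drop = FALSE]
  ev$month <- format(as.Date(fmt_ts(ev$onset_ts)), "%Y-%m")

  counts <- lapply(months, function(m) {
    em <- ev[ev$month == m, , drop = FALSE]
    cls <- table(factor(em$classification, levels = CLASSIFICATIONS))
    row <- tibble::tibble(month = m, n_events = nrow(em))
    for (cl in CLASSIFICATIONS) row[[cl]] <- as.integer(cls[[cl]])
    row
  })
  out <- dplyr::bind_rows(counts)

  out$patient_days <- vapply(seq_along(months), function(i) {
    patient_days(episodes, c(max(month_start[i], period[1]),
                             min(as.Date(month_end[i]), period[2])))
  }, numeric(1))
  out$rate_per_1000_patient_days <-
    ifelse(out$patient_days > 0, 1000 * out$n_events / out$patient_days, NA_real_)

  if ("confirmation_ts" %in% names(events)) {
    ds <- delay_stats(events)
    out <- dplyr::left_join(out, ds$monthly, by = "month")
    names(out)[names(out) == "n"] <- "n_confirmed"
    out$n_confirmed[is.na(out$n_confirmed)] <- 0L
  } else {
    out$n_confirmed <- 0L
    out$mean_delay_days <- NA_real_
    out$sd_delay_days <- NA_real_
  }
  out
}
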