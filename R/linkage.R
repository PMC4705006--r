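#' Link re-admissions into hospitalization episodes
#'
#' Re-admissions within `gap_days` calendar days of the previous discharge
#' (inclusive: a gap of exactly `gap_days` merges) are linked, transitively,
#' to the previous hospital stay and treated as a single hospitalization
#' episode. The healthcare-associated clock of downstream detection starts
#' at the first admission of the merged episode.
#'
#' @param stays a validated stays tibble (see [records]).
#' @param gap_days non-negative integer linkage window in calendar days
#'   (default 2).
#' @return an episode tibble with one row per episode: `episode_id`,
#'   `patient_id`, `episode_start_ts`, `episode_end_ts` (NA while any stay
#'   is open), `n_stays` and a `stays` list-column holding the member
#'   stays (`stay_id`, `admission_ts`, `discharge_ts`).
#' @examples
#' st <- tibble::tibble(
#'   patient_id = "P1", stay_id = c("S1", "S2"),
#'   admission_ts = c("2012-10-01T08:00", "2012-10-07T09:00"),
#'   discharge_ts = c("2012-10-05T10:00", "2012-10-12T10:00"),
#'   birth_date = "1960-01-01", sex = "F"
#' )
#' link_stays(validate_stays(st))  # gap of 2 days: one episode
#' @export
link_stays <- function(stays, gap_days = 2) {
  if (!is.numeric(gap_days) || length(gap_days) != 1 || is.na(gap_days) || gap_days < 0) {
    abort_habsi("gap_days must be a single non-negative number")
  }
  st <- tibble::as_tibble(stays)
  if (!nrow(st)) {
    return(tibble::tibble(episode_id = character(0), patient_id = character(0),
                          episode_start_ts = parse_ts(character(0)),
                          episode_end_ts = parse_ts(character(0)),
                          n_stays = integer(0), stays = list()))
  }
  st <- st[order(st$patient_id, st$admission_ts, st$stay_id), ]
  prev_discharge <- dplyr::lag(st$discharge_ts)
  prev_open <- dplyr::lag(is.na(st$discharge_ts))
  same_patient <- st$patient_id == dplyr::lag(st$patient_id)
  same_patient[1] <- FALSE
  overlap <- same_patient & (prev_open | st$admission_ts < prev_discharge)
  overlap[is.na(overlap)] <- FALSE
  if (any(overlap)) {
    bad <- st$stay_id[overlap][1]
    abort_habsi(paste0("overlapping stays for one patient (stay ", bad, ")"),
                class = "habsi_data_error")
  }
  gap <- as.numeric(as.Date(fmt_ts(st$admission_ts)) -
                      as.Date(fmt_ts(prev_discharge)))
  linked <- same_patient & !is.na(gap) & gap <= gap_days
  ep_index <- cumsum(!linked)
  st$.ep <- ep_index
  eps <- st |>
    dplyr::group_by(.data$.ep) |>
    dplyr::summarise(
      patient_id = .data$patient_id[1],
      episode_start_ts = min(.data$admission_ts),
      episode_end_ts = if (any(is.na(.data$discharge_ts))) parse_ts(NA)
                       else max(.data$discharge_ts),
      n_stays = dplyr::n(),
      stays = list(dplyr::pick("stay_id", "admission_ts", "discharge_ts")),
      .groups = "drop"
    )
  eps <- eps[order(eps$patient_id, eps$episode_start_ts), ]
  eps <- eps |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(episode_id = paste0(.data$patient_id, "-E",
                                      sprintf("%02d", dplyr::row_number()))) |>
    dplyr::ungroup()
  eps[, c("episode_id", "patient_id", "episode_start_ts", "episode_end_ts",
          "n_stays", "stays")]
}

#' Count patient-days over a reporting period
#'
#' Sums, over the member stays of every episode, the calendar days that
#' overlap the period. The admission day counts and the discharge day does
#' not (census convention), so a same-day admission and discharge
#' contributes zero. An open (not yet discharged) stay counts through the
#' end of the period. Gap days between linked stays of one episode are not
#' counted.
#'
#' @param episodes an episode tibble from [link_stays()].
#' @param period a length-2 `Date` (or coercible) vector
#'   `c(first_day, last_day)`, inclusive.
#' @return integer number of patient-days.
#' @export
patient_days <- function(episodes, period) {
  period <- parse_date(period)
  if (length(period) != 2 || any(is.na(period)) || period[2] < period[1]) {
    abort_habsi("period must be c(first_day, last_day) with last >= first")
  }
  if (!nrow(episodes)) return(0L)
  st <- dplyr::bind_rows(episodes$stays)
  adm <- as.Date(fmt_ts(st$admission_ts))
  dis <- as.Date(fmt_ts(st$discharge_ts))
  dis[is.na(dis)] <- period[2] + 1  # open stay occupies through period end
  lo <- pmax(adm, period[1])
  hi <- pmin(dis - 1, period[2])
  as.integer(sum(pmax(0, as.numeric(hi - lo) + 1)))
}
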