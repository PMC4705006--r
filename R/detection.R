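#' The 48-hour hospital-acquired rule
#'
#' A blood specimen is healthcare-associated when its laboratory log-in
#' time (the collection-time proxy) is 48 hours or more after admission --
#' inclusive at exactly 48 h. For episodes merged across a short
#' re-admission gap the clock starts at the first admission of the episode.
#'
#' @param login_ts POSIXct (or parseable) specimen log-in time(s).
#' @param episode a single-row episode tibble from [link_stays()].
#' @param config a [habsi_config].
#' @return logical vector, one per `login_ts`.
#' @export
is_healthcare_associated <- function(login_ts, episode, config = habsi_config()) {
  login_ts <- parse_ts(login_ts)
  start <- episode$episode_start_ts[1]
  end <- episode$episode_end_ts[1]
  outside <- login_ts < start | (!is.na(end) & login_ts > end)
  if (any(outside)) {
    abort_habsi("specimen log-in outside its episode: mis-joined data",
                class = "habsi_data_error")
  }
  hours_between(start, login_ts) >= config$min_hai_hours
}

# age-banded sign flags for a set of vital rows; birth_date may be a single
# date or a vector aligned with vitals
vital_flags <- function(vitals, config, birth_date) {
  if (!nrow(vitals)) {
    return(tibble::tibble(fever = logical(0), hypothermia = logical(0),
                          tachycardia = logical(0), tachypnea = logical(0)))
  }
  age_days <- as.numeric(as.Date(fmt_ts(vitals$ts)) - parse_date(birth_date))
  pediatric <- !is.na(age_days) & age_days <= config$pediatric_age_max_days
  hr_max <- ifelse(pediatric, config$pediatric_hr_max, config$adult_hr_max)
  rr_max <- ifelse(pediatric, config$pediatric_rr_max, config$adult_rr_max)
  tibble::tibble(
    fever = !is.na(vitals$temperature_c) & vitals$temperature_c > config$fever_c,
    hypothermia = !is.na(vitals$temperature_c) & vitals$temperature_c < config$hypothermia_c,
    tachycardia = !is.na(vitals$heart_rate_bpm) & vitals$heart_rate_bpm > hr_max,
    tachypnea = !is.na(vitals$respiratory_rate_pm) & vitals$respiratory_rate_pm > rr_max
  )
}

#' Screen vital signs for infection-related flags in a window
#'
#' Fever is any temperature strictly above the configured threshold
#' (default 38.0 degrees C; a reading of exactly 38.0 is not fever),
#' hypothermia strictly below 36.0; tachycardia and tachypnea use
#' age-banded thresholds (pediatric band: age at measurement no more than
#' `pediatric_age_max_days`). Absent vitals give all-false flags.
#'
#' @param vitals a vitals tibble for one patient (see [records]).
#' @param window length-2 POSIXct (or parseable) `c(start, end)`.
#' @param config a [habsi_config].
#' @param birth_date the patient's birth date (for age-banded thresholds);
#'   NA treats the patient as adult.
#' @return a list of class `habsi_signflags`: `fever`, `hypothermia`,
#'   `tachycardia`, `tachypnea` (logicals) and the `window`.
#' @export
screen_signs <- function(vitals, window, config = habsi_config(), birth_date = NA) {
  window <- parse_ts(window)
  if (length(window) != 2 || any(is.na(window)) || window[2] < window[1]) {
    abort_habsi("window must be c(start, end) with end >= start")
  }
  v <- vitals[vitals$ts >= window[1] & vitals$ts <= window[2], , drop = FALSE]
  fl <- vital_flags(v, config, birth_date)
  structure(list(
    fever = any(fl$fever), hypothermia = any(fl$hypothermia),
    tachycardia = any(fl$tachycardia), tachypnea = any(fl$tachypnea),
    window = window
  ), class = "habsi_signflags")
}

#' @export
print.habsi_signflags <- function(x, ...) {
  on <- names(which(unlist(x[c("fever", "hypothermia", "tachycardia", "tachypnea")])))
  cat("<signflags ", fmt_ts(x$window[1]), " .. ", fmt_ts(x$window[2]), "> ",
      if (length(on)) paste(on, collapse = ", ") else "none", "\n", sep = "")
  invisible(x)
}

# organisms reported for a culture once revisions inside the recall window
# are applied; each revision replaces the whole set, later ones are ignored
effective_organisms <- function(organisms, revisions, report_final_ts, recall_days) {
  if (is.null(revisions) || !nrow(revisions)) return(organisms)
  cutoff <- report_final_ts + recall_days * 86400
  ok <- revisions$revision_ts <= cutoff
  if (!any(ok)) return(organisms)
  revisions$organisms[[max(which(ok))]]
}

apply_revisions <- function(cultures, config) {
  has_rev <- vapply(cultures$revisions, function(r) !is.null(r) && nrow(r) > 0, logical(1))
  orgs <- cultures$organisms
  if (any(has_rev)) {
    orgs[has_rev] <- purrr::pmap(
      list(cultures$organisms[has_rev], cultures$revisions[has_rev],
           cultures$report_final_ts[has_rev]),
      function(o, r, f) effective_organisms(o, r, f, config$recall_days)
    )
  }
  orgs
}

#' Confirm organism growth in an episode's blood cultures
#'
#' Report revisions dated within `recall_days` of the final report are
#' applied first (each revision replaces the organism set; later revisions
#' are ignored). A recognized (non-commensal) pathogen in any blood culture
#' is confirmed immediately. A common skin commensal is confirmed only when
#' the same organism appears in at least two blood specimens from separate
#' draws with log-ins at most `commensal_window_days` calendar days apart
#' and at least one sign flag is present within
#' `commensal_sign_window_hours` of the first draw of the corroborating
#' pair.
#'
#' @param blood_cultures blood-culture rows for one episode (see [records]).
#' @param vitals the patient's vitals tibble (for the sign requirement).
#' @param config a [habsi_config].
#' @param birth_date the patient's birth date.
#' @return `blood_cultures` with a `confirmed` list-column holding the
#'   confirmed organism set per specimen (possibly empty).
#' @export
confirm_organisms <- function(blood_cultures, vitals, config = habsi_config(),
                              birth_date = NA) {
  cu <- tibble::as_tibble(blood_cultures)
  if (!nrow(cu)) {
    cu$confirmed <- list()
    return(cu)
  }
  cu$eff <- apply_revisions(cu, config)
  fl <- vital_flags(vitals, config, birth_date)
  any_flag <- fl$fever | fl$hypothermia | fl$tachycardia | fl$tachypnea
  flagged <- vitals[any_flag, , drop = FALSE]
  out <- confirm_blood_group(cu, flagged, config)
  out$eff <- NULL
  out
}

#' Detect HABSI candidates by screening an EMR bundle
#'
#' Implements the daily-screening detection algorithm: every confirmed
#' organism-positive blood specimen that satisfies the 48-hour
#' hospital-acquired rule becomes one culture-pathway candidate (onset =
#' specimen log-in). In episodes with no such specimen near a sign, the
#' clinical-sepsis pathway emits at most one candidate per episode at the
#' earliest sign (itself at least 48 h after episode start) that has a new
#' antimicrobial order within 48 h after it, no confirmed positive blood
#' culture within +/- 48 h, and no confirmed positive non-blood site
#' culture within +/- 7 days.
#'
#' @param bundle a [habsi_bundle].
#' @param config a [habsi_config].
#' @param episodes optionally, pre-computed episodes from [link_stays()].
#' @return a candidate tibble: `candidate_id`, `patient_id`, `episode_id`,
#'   `onset_ts`, `pathway` (`culture`/`sepsis`), `organisms`,
#'   `source_specimens` (list-columns), and the four sign flags evaluated
#'   within +/- 24 h of onset.
#' @export
detect_candidates <- function(bundle, config = habsi_config(), episodes = NULL) {
  stopifnot(inherits(bundle, "habsi_bundle"))
  if (is.null(episodes)) episodes <- link_stays(bundle$stays, config$readmit_gap_days)
  patients <- bundle$stays |>
    dplyr::distinct(.data$patient_id, .keep_all = TRUE) |>
    dplyr::select("patient_id", "birth_date")

  empty_cand <- tibble::tibble(
    candidate_id = character(0), patient_id = character(0),
    episode_id = character(0), onset_ts = parse_ts(character(0)),
    pathway = character(0), organisms = list(), source_specimens = list(),
    fever = logical(0), hypothermia = logical(0),
    tachycardia = logical(0), tachypnea = logical(0)
  )
  if (!nrow(episodes)) return(empty_cand)

  # vital rows carrying at least one sign flag (the only ones any rule uses)
  vit <- dplyr::inner_join(bundle$vitals, patients, by = "patient_id")
  fl <- vital_flags(vit, config, vit$birth_date)
  flagged <- dplyr::bind_cols(vit, fl)
  flagged <- flagged[fl$fever | fl$hypothermia | fl$tachycardia | fl$tachypnea, ,
                     drop = FALSE]

  # assign cultures to episodes by patient + containment of login time
  ep_flat <- episodes |>
    dplyr::select("episode_id", "patient_id", "episode_start_ts", "episode_end_ts")
  cu <- dplyr::inner_join(bundle$cultures, ep_flat, by = "patient_id",
                          relationship = "many-to-many")
  inside <- cu$login_ts >= cu$episode_start_ts &
    (is.na(cu$episode_end_ts) | cu$login_ts <= cu$episode_end_ts)
  cu <- cu[inside, , drop = FALSE]
  cu <- dplyr::inner_join(cu, patients, by = "patient_id")
  cu$eff <- apply_revisions(cu, config)

  blood <- cu[cu$specimen_type == "blood", , drop = FALSE]
  site <- cu[!(cu$specimen_type %in% c("blood", "catheter_tip")), , drop = FALSE]
  site_pos <- site[vapply(site$eff,
                          function(o) any(!is_commensal(o, config)), logical(1)), ,
                   drop = FALSE]

  # per-episode organism confirmation for blood specimens
  blood$confirmed <- replicate(nrow(blood), character(0), simplify = FALSE)
  if (nrow(blood)) {
    needs_pair <- split(seq_len(nrow(blood)), blood$episode_id)
    for (idx in needs_pair) {
      b <- blood[idx, , drop = FALSE]
      pv <- flagged[flagged$patient_id == b$patient_id[1], , drop = FALSE]
      b2 <- confirm_blood_group(b, pv, config)
      blood$confirmed[idx] <- b2$confirmed
    }
  }
  pos <- blood[lengths(blood$confirmed) > 0, , drop = FALSE]

  # culture-pathway candidates: one per confirmed healthcare-associated draw
  cands <- list()
  if (nrow(pos)) {
    ha <- hours_between(pos$episode_start_ts, pos$login_ts) >= config$min_hai_hours
    pos <- pos[ha, , drop = FALSE]
    if (nrow(pos)) {
      sf <- candidate_signs(pos$patient_id, pos$login_ts, flagged,
                            config$commensal_sign_window_hours)
      cands$culture <- tibble::tibble(
        patient_id = pos$patient_id, episode_id = pos$episode_id,
        onset_ts = pos$login_ts, pathway = "culture",
        organisms = pos$confirmed,
        source_specimens = as.list(pos$specimen_id),
        fever = sf$fever, hypothermia = sf$hypothermia,
        tachycardia = sf$tachycardia, tachypnea = sf$tachypnea
      )
    }
  }

  # clinical-sepsis pathway
  csep <- csep_candidates(episodes, flagged, blood, site_pos, bundle$abx, config)
  cands$sepsis <- csep

  out <- dplyr::bind_rows(cands)
  if (!nrow(out)) return(empty_cand)
  out <- out[order(out$patient_id, out$onset_ts, out$pathway), ]
  out$candidate_id <- sprintf("C%05d", seq_len(nrow(out)))
  out[, names(empty_cand)]
}

# confirmation within one episode's blood cultures, given pre-flagged vitals
confirm_blood_group <- function(b, flagged_vitals, config) {
  eff <- b$eff
  comm <- lapply(eff, function(o) o[is_commensal(o, config)])
  confirmed <- lapply(eff, function(o) o[!is_commensal(o, config)])
  all_comm <- unique(unlist(comm))
  if (length(all_comm)) {
    sign_ts <- flagged_vitals$ts
    w_sec <- config$commensal_sign_window_hours * 3600
    for (org in all_comm) {
      idx <- which(vapply(comm, function(o) org %in% o, logical(1)))
      if (length(idx) < 2) next
      logins <- b$login_ts[idx]
      dates <- as.Date(fmt_ts(logins))
      for (a in seq_along(idx)) {
        for (bb in seq_along(idx)) {
          if (a >= bb) next
          if (abs(as.numeric(dates[a] - dates[bb])) > config$commensal_window_days) next
          first <- min(logins[a], logins[bb])
          has_sign <- length(sign_ts) &&
            any(abs(as.numeric(sign_ts) - as.numeric(first)) <= w_sec)
          if (has_sign) {
            for (k in idx[c(a, bb)]) confirmed[[k]] <- union(confirmed[[k]], org)
          }
        }
      }
    }
  }
  b$confirmed <- confirmed
  b
}

candidate_signs <- function(patient_id, onset_ts, flagged, window_hours) {
  w <- window_hours * 3600
  out <- tibble::tibble(fever = logical(length(onset_ts)),
                        hypothermia = logical(length(onset_ts)),
                        tachycardia = logical(length(onset_ts)),
                        tachypnea = logical(length(onset_ts)))
  if (!nrow(flagged) || !length(onset_ts)) return(out)
  for (i in seq_along(onset_ts)) {
    fv <- flagged[flagged$patient_id == patient_id[i] &
                    abs(as.numeric(flagged$ts) - as.numeric(onset_ts[i])) <= w, ,
                  drop = FALSE]
    out$fever[i] <- any(fv$fever)
    out$hypothermia[i] <- any(fv$hypothermia)
    out$tachycardia[i] <- any(fv$tachycardia)
    out$tachypnea[i] <- any(fv$tachypnea)
  }
  out
}

csep_candidates <- function(episodes, flagged, blood, site_pos, abx, config) {
  if (!nrow(flagged)) return(NULL)
  ep_flat <- episodes |>
    dplyr::select("episode_id", "patient_id", "episode_start_ts", "episode_end_ts")
  sg <- dplyr::inner_join(flagged, ep_flat, by = "patient_id",
                          relationship = "many-to-many")
  inside <- sg$ts >= sg$episode_start_ts &
    (is.na(sg$episode_end_ts) | sg$ts <= sg$episode_end_ts)
  sg <- sg[inside, , drop = FALSE]
  sg <- sg[hours_between(sg$episode_start_ts, sg$ts) >= config$min_hai_hours, ,
           drop = FALSE]
  if (!nrow(sg)) return(NULL)

  # a new antimicrobial order within the treatment window after the sign
  has_abx <- logical(nrow(sg))
  ab_by_pat <- split(abx$start_ts, abx$patient_id)
  w_abx <- config$csep_abx_window_hours * 3600
  for (i in seq_len(nrow(sg))) {
    starts <- ab_by_pat[[sg$patient_id[i]]]
    has_abx[i] <- !is.null(starts) &&
      any(starts >= sg$ts[i] & starts <= sg$ts[i] + w_abx)
  }
  sg <- sg[has_abx, , drop = FALSE]
  if (!nrow(sg)) return(NULL)

  # no confirmed positive blood culture near the sign, no positive site culture
  pos_blood <- blood[lengths(blood$confirmed) > 0, , drop = FALSE]
  w_blood <- config$csep_blood_window_hours * 3600
  w_site <- config$csep_site_window_days * 86400
  keep <- logical(nrow(sg))
  for (i in seq_len(nrow(sg))) {
    pb <- pos_blood$login_ts[pos_blood$patient_id == sg$patient_id[i]]
    near_blood <- length(pb) && any(abs(as.numeric(pb) - as.numeric(sg$ts[i])) <= w_blood)
    ps <- site_pos$login_ts[site_pos$patient_id == sg$patient_id[i]]
    near_site <- length(ps) && any(abs(as.numeric(ps) - as.numeric(sg$ts[i])) <= w_site)
    keep[i] <- !near_blood && !near_site
  }
  sg <- sg[keep, , drop = FALSE]
  if (!nrow(sg)) return(NULL)

  first <- sg |>
    dplyr::group_by(.data$episode_id) |>
    dplyr::slice_min(.data$ts, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  tibble::tibble(
    patient_id = first$patient_id, episode_id = first$episode_id,
    onset_ts = first$ts, pathway = "sepsis",
    organisms = replicate(nrow(first), character(0), simplify = FALSE),
    source_specimens = replicate(nrow(first), character(0), simplify = FALSE),
    fever = first$fever, hypothermia = first$hypothermia,
    tachycardia = first$tachycardia, tachypnea = first$tachypnea
  )
}
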