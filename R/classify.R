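#' Merge candidates into events (polymicrobial and persistent BSI criteria)
#'
#' Replays each episode's candidates chronologically. Candidates of the
#' same pathway whose onsets fall within `polymicrobial_hours` of an
#' event's onset merge into that event with the union organism set
#' (polymicrobial BSI). A later candidate sharing at least one organism
#' with an earlier event and with onset at most `persistent_days` days
#' after the event onset is absorbed into it (persistent BSI: repeated
#' isolation of the same organism is one continuing infection, not a new
#' event); the window is anchored at the event onset and is not extended
#' by absorbed candidates. Otherwise the candidate opens a new event. Both
#' criteria exist to eliminate duplicate counting; setting a window to 0
#' disables that merge entirely. The replay is iterated to a fixed point,
#' so the result is stable under re-merging (a merged union set that newly
#' overlaps an earlier event inside the persistent window still collapses).
#'
#' @param candidates a candidate tibble from [detect_candidates()].
#' @param config a [habsi_config] (uses `polymicrobial_hours`,
#'   `persistent_days`).
#' @return a pre-classification event tibble: `event_id`, `patient_id`,
#'   `episode_id`, `onset_ts`, `pathway`, `organisms`, `source_specimens`,
#'   `n_candidates`, `confirmation_ts` (NA; filled by the confirming
#'   reviewer downstream).
#' @export
merge_events <- function(candidates, config = habsi_config()) {
  cand <- tibble::as_tibble(candidates)
  empty <- tibble::tibble(
    event_id = character(0), patient_id = character(0), episode_id = character(0),
    onset_ts = parse_ts(character(0)), pathway = character(0),
    organisms = list(), source_specimens = list(), n_candidates = integer(0),
    confirmation_ts = parse_ts(character(0))
  )
  if (!nrow(cand)) return(empty)
  state <- list(
    patient = cand$patient_id, episode = cand$episode_id,
    onset = as.numeric(cand$onset_ts), pathway = cand$pathway,
    orgs = cand$organisms, specs = cand$source_specimens,
    weight = rep(1L, nrow(cand))
  )
  # a single chronological replay can itself create new organism overlaps
  # (a merged event's union set may now intersect an earlier event inside
  # the persistent window), so replay until the event set is a fixed point;
  # each extra pass only merges further, conserving candidate counts
  repeat {
    merged <- replay_merge(state, config)
    if (length(merged$onset) == length(state$onset)) {
      state <- merged
      break
    }
    state <- merged
  }
  out <- tibble::tibble(
    patient_id = state$patient, episode_id = state$episode,
    onset_ts = trunc_minute(as.POSIXct(state$onset, origin = "1970-01-01",
                                       tz = HABSI_TZ)),
    pathway = state$pathway, organisms = state$orgs,
    source_specimens = state$specs, n_candidates = state$weight,
    confirmation_ts = parse_ts(rep(NA_character_, length(state$onset)))
  )
  out <- out[order(out$onset_ts, out$patient_id, out$episode_id), ]
  out$event_id <- sprintf("E%05d", seq_len(nrow(out)))
  out[, names(empty)]
}

# one chronological replay pass over candidate-shaped state
replay_merge <- function(state, config) {
  ord <- order(state$episode, state$onset, state$pathway,
               vapply(state$specs, paste, character(1), collapse = "|"))
  poly_sec <- config$polymicrobial_hours * 3600
  pers_sec <- config$persistent_days * 86400
  n_ev <- 0L
  ev <- list(patient = character(0), episode = character(0), onset = numeric(0),
             pathway = character(0), orgs = list(), specs = list(),
             weight = integer(0))
  for (i in ord) {
    epi <- state$episode[i]
    pw <- state$pathway[i]
    on <- state$onset[i]
    orgs <- normalize_organism(state$orgs[[i]])
    target <- 0L
    if (n_ev > 0) {
      in_epi <- which(ev$episode == epi)
      if (config$polymicrobial_hours > 0) {
        hit <- in_epi[ev$pathway[in_epi] == pw &
                        abs(on - ev$onset[in_epi]) <= poly_sec]
        if (length(hit)) target <- hit[1]
      }
      if (target == 0L && config$persistent_days > 0 && length(orgs)) {
        hit <- in_epi[vapply(in_epi, function(j) {
          length(intersect(orgs, normalize_organism(ev$orgs[[j]]))) > 0 &&
            (on - ev$onset[j]) >= 0 && (on - ev$onset[j]) <= pers_sec
        }, logical(1))]
        if (length(hit)) target <- hit[1]
      }
    }
    if (target == 0L) {
      n_ev <- n_ev + 1L
      ev$patient[n_ev] <- state$patient[i]
      ev$episode[n_ev] <- epi
      ev$pathway[n_ev] <- pw
      ev$onset[n_ev] <- on
      ev$orgs[[n_ev]] <- state$orgs[[i]]
      ev$specs[[n_ev]] <- state$specs[[i]]
      ev$weight[n_ev] <- state$weight[i]
    } else {
      ev$onset[target] <- min(ev$onset[target], on)
      ev$orgs[[target]] <- union(ev$orgs[[target]], state$orgs[[i]])
      ev$specs[[target]] <- union(ev$specs[[target]], state$specs[[i]])
      ev$weight[target] <- ev$weight[target] + state$weight[i]
    }
  }
  ev
}

#' Classify a bloodstream-infection event
#'
#' Classification precedence is total and deterministic:
#' CSEP > SEC > PRIM_CRBSI > PRIM_CLABSI > PRIM_OTHER.
#'
#' * `CSEP`: the event came through the clinical-sepsis pathway (no
#'   organisms).
#' * `SEC` (secondary BSI): a confirmed non-blood, non-catheter-tip culture
#'   within +/- `secondary_window_days` of onset carries a matching
#'   (genus + species, non-commensal) organism.
#' * `PRIM_CRBSI` (catheter-related): a central line overlaps
#'   `[onset - line_lookback_hours, onset]` and a catheter-tip specimen
#'   within +/- `tip_window_days` carries a matching organism.
#' * `PRIM_CLABSI` (line-associated, other than CRBSI): the line overlap
#'   holds without tip concordance.
#' * `PRIM_OTHER`: all remaining primary events.
#'
#' @param event a single-row event tibble from [merge_events()].
#' @param non_blood_cultures the patient's non-blood culture rows.
#' @param devices the patient's device intervals.
#' @param config a [habsi_config].
#' @return one of `"PRIM_CRBSI"`, `"PRIM_CLABSI"`, `"PRIM_OTHER"`,
#'   `"SEC"`, `"CSEP"`.
#' @export
classify <- function(event, non_blood_cultures, devices, config = habsi_config()) {
  if (event$pathway[1] == "sepsis") return("CSEP")
  onset <- as.numeric(event$onset_ts[1])
  ev_orgs <- normalize_organism(event$organisms[[1]])

  nb <- tibble::as_tibble(non_blood_cultures)
  nb <- nb[nb$specimen_type != "blood", , drop = FALSE]
  if (nrow(nb)) {
    if (!"eff" %in% names(nb)) nb$eff <- apply_revisions(nb, config)
  } else {
    nb$eff <- list()
  }

  w_sec <- config$secondary_window_days * 86400
  sites <- nb[nb$specimen_type != "catheter_tip" &
                abs(as.numeric(nb$login_ts) - onset) <= w_sec, , drop = FALSE]
  sec_match <- any(vapply(sites$eff, function(o) {
    o <- normalize_organism(o[!is_commensal(o, config)])
    length(intersect(o, ev_orgs)) > 0
  }, logical(1)))
  if (isTRUE(sec_match)) return("SEC")

  dv <- tibble::as_tibble(devices)
  dv <- dv[dv$device_type == "central_line", , drop = FALSE]
  look <- onset - config$line_lookback_hours * 3600
  line <- any(as.numeric(dv$start_ts) <= onset &
                (is.na(dv$end_ts) | as.numeric(dv$end_ts) >= look))
  if (!isTRUE(line)) return("PRIM_OTHER")

  w_tip <- config$tip_window_days * 86400
  tips <- nb[nb$specimen_type == "catheter_tip" &
               abs(as.numeric(nb$login_ts) - onset) <= w_tip, , drop = FALSE]
  tip_match <- any(vapply(tips$eff, function(o) {
    length(intersect(normalize_organism(o), ev_orgs)) > 0
  }, logical(1)))
  if (isTRUE(tip_match)) "PRIM_CRBSI" else "PRIM_CLABSI"
}

classify_events <- function(events, bundle, config) {
  if (!nrow(events)) {
    events$classification <- character(0)
    return(events)
  }
  nb <- bundle$cultures[bundle$cultures$specimen_type != "blood", , drop = FALSE]
  nb$eff <- apply_revisions(nb, config)
  nb_by_pat <- split(nb, nb$patient_id)
  dv_by_pat <- split(bundle$devices, bundle$devices$patient_id)
  events$classification <- vapply(seq_len(nrow(events)), function(i) {
    pid <- events$patient_id[i]
    classify(events[i, ], nb_by_pat[[pid]] %||% nb[0, ],
             dv_by_pat[[pid]] %||% bundle$devices[0, ], config)
  }, character(1))
  events
}

#' Run the full surveillance pipeline
#'
#' Deterministic composition of [link_stays()], [detect_candidates()],
#' [merge_events()] and [classify()], with a funnel report of counts at
#' each stage (patients screened, episodes, blood cultures, candidates by
#' pathway, candidates absorbed by deduplication, events by class).
#'
#' @param bundle a [habsi_bundle].
#' @param config a [habsi_config].
#' @return an object of class `habsi_result`: list with `events` (the
#'   classified event tibble), `funnel` (named list of stage counts) and
#'   `config`.
#' @export
run_pipeline <- function(bundle, config = habsi_config()) {
  stopifnot(inherits(bundle, "habsi_bundle"))
  episodes <- link_stays(bundle$stays, config$readmit_gap_days)
  candidates <- detect_candidates(bundle, config, episodes = episodes)
  events <- merge_events(candidates, config)
  events <- classify_events(events, bundle, config)
  events <- events[, c("event_id", "patient_id", "episode_id", "onset_ts",
                       "organisms", "classification", "source_specimens",
                       "confirmation_ts", "n_candidates")]
  by_class <- as.list(table(factor(events$classification, levels = CLASSIFICATIONS)))
  funnel <- list(
    n_patients = dplyr::n_distinct(bundle$stays$patient_id),
    n_stays = nrow(bundle$stays),
    n_episodes = nrow(episodes),
    n_blood_cultures = sum(bundle$cultures$specimen_type == "blood"),
    n_candidates_culture = sum(candidates$pathway == "culture"),
    n_candidates_sepsis = sum(candidates$pathway == "sepsis"),
    n_candidates = nrow(candidates),
    n_candidates_absorbed = nrow(candidates) - nrow(events),
    n_events = nrow(events),
    events_by_classification = lapply(by_class, as.integer)
  )
  structure(list(events = events, funnel = funnel, config = config),
            class = "habsi_result")
}

#' @export
print.habsi_result <- function(x, ...) {
  f <- x$funnel
  cat("<habsi_result>\n")
  cat(sprintf("  %d patients, %d episodes, %d blood cultures\n",
              f$n_patients, f$n_episodes, f$n_blood_cultures))
  cat(sprintf("  candidates: %d culture + %d sepsis; %d absorbed by dedup\n",
              f$n_candidates_culture, f$n_candidates_sepsis, f$n_candidates_absorbed))
  cat(sprintf("  events: %d (%s)\n", f$n_events,
              paste(names(f$events_by_classification),
                    unlist(f$events_by_classification),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
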