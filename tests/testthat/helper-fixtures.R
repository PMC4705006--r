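# Builders and independent oracles used across the suite. All fixtures are
# constructed in code; nothing is read from disk.

stay_row <- function(pid, stay, adm, dis, birth = "1960-01-01", sex = "F") {
  tibble::tibble(patient_id = pid, stay_id = stay, admission_ts = adm,
                 discharge_ts = dis, birth_date = birth, sex = sex)
}

culture_fixture <- function(spec, pid, login, type = "blood", orgs = character(0),
                            final = NULL, revisions = NULL) {
  login_ts <- habsi:::parse_ts(login)
  tibble::tibble(
    specimen_id = spec, patient_id = pid, login_ts = login_ts,
    specimen_type = type, organisms = list(orgs),
    report_final_ts = if (is.null(final)) login_ts + 48 * 3600
                      else habsi:::parse_ts(final),
    revisions = list(revisions %||% habsi:::empty_revisions())
  )
}

vital_row <- function(pid, ts, temp = NA, hr = NA, rr = NA) {
  tibble::tibble(patient_id = pid, ts = ts, temperature_c = temp,
                 heart_rate_bpm = hr, respiratory_rate_pm = rr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force transitive closure over pairwise calendar-gap checks;
# independent of the grouping logic inside link_stays()
linkage_oracle <- function(stays, gap_days) {
  st <- stays
  st$adm_d <- as.Date(format(habsi:::parse_ts(st$admission_ts), "%Y-%m-%d"))
  st$dis_d <- as.Date(format(habsi:::parse_ts(st$discharge_ts), "%Y-%m-%d"))
  n <- nrow(st)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j || comp[i] == comp[j]) next
        if (st$patient_id[i] != st$patient_id[j]) next
        gap_ij <- as.numeric(st$adm_d[j] - st$dis_d[i])
        gap_ji <- as.numeric(st$adm_d[i] - st$dis_d[j])
        linked <- (gap_ij >= 0 && gap_ij <= gap_days) ||
          (gap_ji >= 0 && gap_ji <= gap_days)
        if (linked) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  split(st$stay_id, comp) |> lapply(sort) |> unname()
}

partition_of_episodes <- function(episodes) {
  lapply(episodes$stays, function(s) sort(s$stay_id)) |> unname()
}

same_partition <- function(a, b) {
  key <- function(p) sort(vapply(p, paste, character(1), collapse = "+"))
  identical(key(a), key(b))
}

# date-enumeration oracle for patient-day counting
patient_days_oracle <- function(episodes, period) {
  period <- as.Date(period)
  total <- 0L
  for (st in episodes$stays) {
    for (k in seq_len(nrow(st))) {
      adm <- as.Date(format(st$admission_ts[k], "%Y-%m-%d"))
      dis <- st$discharge_ts[k]
      dis <- if (is.na(dis)) period[2] + 1 else as.Date(format(dis, "%Y-%m-%d"))
      if (dis <= adm) next
      days <- seq(adm, dis - 1, by = "day")
      total <- total + sum(days >= period[1] & days <= period[2])
    }
  }
  total
}

# closed-form oracles, written straight from the textbook formulas
kappa_oracle <- function(tp, fn, fp, tn) {
  n <- tp + fn + fp + tn
  po <- (tp + tn) / n
  pe <- ((tp + fn) / n) * ((tp + fp) / n) + ((tn + fp) / n) * ((tn + fn) / n)
  (po - pe) / (1 - pe)
}

pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# one shared big cohort with error modes off, generated once per session
shared_cohort_env <- new.env(parent = emptyenv())
clean_cohort_10k <- function() {
  if (is.null(shared_cohort_env$cohort)) {
    shared_cohort_env$cohort <- generate_cohort(cohort_config(
      n_patients = 10000, seed = 20121001,
      contamination_prob = 0, revision_after_recall_prob = 0))
  }
  shared_cohort_env$cohort
}

# a 12-patient bundle whose expected event list was derived by applying the
# documented rules by hand; returns the bundle plus the expectations
hand_fixture <- function() {
  adm <- "2012-10-01T00:00"
  stays <- dplyr::bind_rows(
    stay_row("H01", "H01-S1", adm, "2012-10-12T12:00"),  # pathogen at 72 h
    stay_row("H02", "H02-S1", adm, "2012-10-10T12:00"),  # pathogen at 24 h only
    stay_row("H03", "H03-S1", adm, "2012-10-12T12:00"),  # CoNS pair + fever + line
    stay_row("H04", "H04-S1", adm, "2012-10-12T12:00"),  # CoNS single draw
    stay_row("H05", "H05-S1", adm, "2012-10-12T12:00"),  # clinical sepsis
    stay_row("H06", "H06-S1", adm, "2012-10-12T12:00"),  # secondary (urine match)
    stay_row("H07", "H07-S1", adm, "2012-10-12T12:00"),  # CRBSI (tip concordant)
    stay_row("H08", "H08-S1", adm, "2012-10-20T12:00"),  # persistent repeat
    stay_row("H09", "H09-S1", adm, "2012-10-12T12:00"),  # polymicrobial
    stay_row("H10", "H10-S1", adm, "2012-10-12T12:00"),  # late revision -> FP type
    stay_row("H11", "H11-S1", adm, "2012-10-12T12:00"),  # in-window revision
    stay_row("H12", "H12-S1", "2012-10-01T00:00", "2012-10-04T00:00"),
    stay_row("H12", "H12-S2", "2012-10-06T00:00", "2012-10-12T00:00")  # linked gap 2
  )
  rev_of <- function(ts, orgs) tibble::tibble(
    revision_ts = habsi:::parse_ts(ts), organisms = list(orgs))
  cultures <- dplyr::bind_rows(
    culture_fixture("X01", "H01", "2012-10-04T00:00", orgs = "Escherichia coli"),
    culture_fixture("X02", "H02", "2012-10-02T00:00", orgs = "Escherichia coli"),
    culture_fixture("X03", "H03", "2012-10-04T08:00",
                    orgs = "Staphylococcus epidermidis"),
    culture_fixture("X04", "H03", "2012-10-04T09:00",
                    orgs = "Staphylococcus epidermidis"),
    culture_fixture("X05", "H04", "2012-10-04T08:00",
                    orgs = "Staphylococcus epidermidis"),
    culture_fixture("X06", "H06", "2012-10-05T00:00", orgs = "Klebsiella pneumoniae"),
    culture_fixture("X07", "H06", "2012-10-04T00:00", type = "urine",
                    orgs = "Klebsiella pneumoniae"),
    culture_fixture("X08", "H07", "2012-10-05T00:00", orgs = "Staphylococcus aureus"),
    culture_fixture("X09", "H07", "2012-10-06T00:00", type = "catheter_tip",
                    orgs = "Staphylococcus aureus"),
    culture_fixture("X10", "H08", "2012-10-04T00:00", orgs = "Pseudomonas aeruginosa"),
    culture_fixture("X11", "H08", "2012-10-14T00:00", orgs = "Pseudomonas aeruginosa"),
    culture_fixture("X12", "H09", "2012-10-04T00:00", orgs = "Escherichia coli"),
    culture_fixture("X13", "H09", "2012-10-04T06:00", orgs = "Klebsiella pneumoniae"),
    culture_fixture("X14", "H10", "2012-10-04T00:00", orgs = "Enterobacter cloacae",
                    revisions = rev_of("2012-10-16T00:00",
                                       "Staphylococcus epidermidis")),
    culture_fixture("X15", "H11", "2012-10-04T00:00", orgs = "Enterobacter cloacae",
                    revisions = rev_of("2012-10-08T00:00",
                                       "Staphylococcus epidermidis")),
    culture_fixture("X16", "H12", "2012-10-06T02:00", orgs = "Escherichia coli")
  )
  vitals <- dplyr::bind_rows(
    vital_row("H03", "2012-10-04T06:00", temp = 38.6),
    vital_row("H04", "2012-10-04T06:00", temp = 38.6),
    vital_row("H05", "2012-10-05T08:00", temp = 39.0),
    vital_row("H06", "2012-10-05T01:00", temp = 38.4)
  )
  devices <- tibble::tibble(
    patient_id = c("H03", "H07"), device_type = "central_line",
    start_ts = "2012-10-01T02:00", end_ts = "2012-10-08T00:00")
  abx <- tibble::tibble(patient_id = "H05", drug_code = "J01DH02",
                        start_ts = "2012-10-05T10:00", end_ts = "2012-10-12T00:00")
  bundle <- habsi_bundle(stays, cultures, vitals, devices, abx)
  expected <- tibble::tibble(
    patient_id = c("H01", "H03", "H05", "H06", "H07", "H08", "H09", "H10", "H12"),
    classification = c("PRIM_OTHER", "PRIM_CLABSI", "CSEP", "SEC", "PRIM_CRBSI",
                       "PRIM_OTHER", "PRIM_OTHER", "PRIM_OTHER", "PRIM_OTHER"),
    n_organisms = c(1L, 1L, 0L, 1L, 1L, 1L, 2L, 1L, 1L)
  )
  list(bundle = bundle, expected = expected,
       negatives = c("H02", "H04", "H11"))
}

# candidate-row builder shared by dedup tests
make_cands <- function(...) {
  rows <- list(...)
  cand <- dplyr::bind_rows(lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    tibble::tibble(
      candidate_id = sprintf("C%03d", i), patient_id = "P1",
      episode_id = "P1-E01", onset_ts = habsi:::parse_ts(r$onset),
      pathway = r$pathway %||% "culture",
      organisms = list(r$orgs %||% character(0)),
      source_specimens = list(r$spec %||% sprintf("S%03d", i)),
      fever = TRUE, hypothermia = FALSE, tachycardia = FALSE, tachypnea = FALSE)
  }))
  cand
}
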