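#' Synthetic cohort configuration
#'
#' Parameters of the seeded synthetic EMR generator. The generator plants
#' HABSI cases that satisfy the documented detection rules by construction
#' (timing, paired draws, signs, devices, site cultures) and plants
#' negatives that exercise each rule boundary: community-onset BSIs
#' (first positive draw < 48 h after admission), uncorroborated
#' single-draw commensal contaminants, persistent-BSI repeat draws, and
#' laboratory reports revised after the recall day.
#'
#' \describe{
#'   \item{n_patients}{cohort size (default 10000).}
#'   \item{period}{`c(first_day, last_day)` of the surveillance month
#'     (default October 2012, 31 days); must span at least 7 days.}
#'   \item{habsi_rate_per_1000_patients}{planted case rate; each patient is
#'     a case independently with probability rate/1000 (default 14.7).}
#'   \item{contamination_prob}{probability a non-case patient contributes a
#'     single uncorroborated commensal blood draw (default 0.02).}
#'   \item{single_draw_prob}{fraction of planted pathogen-case blood
#'     specimens obtained through a single draw rather than the routine
#'     paired sets (default 0.0123); a recognized pathogen confirms on one
#'     draw, so this is a realism statistic, not an error mode.}
#'   \item{commensal_single_draw_prob}{error mode: probability the
#'     corroborating second draw of a planted commensal-organism case is
#'     withheld, producing a false negative of the fever/corroboration
#'     type (default 0).}
#'   \item{revision_after_recall_prob}{error mode: probability a non-case
#'     patient carries a blood culture whose final pathogen report is
#'     corrected to a commensal contaminant only after the recall day,
#'     producing a false positive (default 0.0005).}
#'   \item{inwindow_revision_prob}{probability of the benign counterpart:
#'     the same correction arrives within the recall window and is applied
#'     (default 0.001).}
#'   \item{readmit_prob}{probability of a re-admission (linked, gap of 1-2
#'     days, for cases; mixed gaps for non-cases; default 0.05).}
#'   \item{subtype_mix}{named probabilities over
#'     PRIM_CRBSI/PRIM_CLABSI/PRIM_OTHER/SEC/CSEP, summing to 1.}
#'   \item{commensal_case_prob}{fraction of planted primary cases caused by
#'     a common skin commensal (default 0.1; secondary cases always use
#'     recognized pathogens).}
#'   \item{community_onset_prob, fever_only_prob, abx_only_prob}{rates of
#'     the remaining planted negative patterns.}
#'   \item{persistent_repeat_prob}{probability a planted case has an extra
#'     positive draw of the same organism 4-10 days after onset (must be
#'     absorbed, not double counted; default 0.3).}
#'   \item{pediatric_prob}{fraction of infants (age at admission at most
#'     one year; default 0.05).}
#'   \item{n_departments}{departments with skewed patient volumes, for
#'     by-place correlation analyses (default 20).}
#'   \item{confirmation_delay_mean_days, confirmation_delay_sd_days}{gamma
#'     model of the reviewer confirmation delay attached to planted cases
#'     (defaults 14.58 and 4.64 days).}
#'   \item{seed}{integer RNG seed.}
#' }
#'
#' @param ... named overrides of the defaults.
#' @return an object of class `habsi_cohort_config`.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    n_patients = 10000L,
    period = c("2012-10-01", "2012-10-31"),
    habsi_rate_per_1000_patients = 14.7,
    contamination_prob = 0.02,
    single_draw_prob = 0.0123,
    commensal_single_draw_prob = 0,
    revision_after_recall_prob = 0.0005,
    inwindow_revision_prob = 0.001,
    readmit_prob = 0.05,
    subtype_mix = c(PRIM_CRBSI = 0.25, PRIM_CLABSI = 0.20, PRIM_OTHER = 0.30,
                    SEC = 0.15, CSEP = 0.10),
    commensal_case_prob = 0.1,
    community_onset_prob = 0.01,
    fever_only_prob = 0.05,
    abx_only_prob = 0.05,
    persistent_repeat_prob = 0.3,
    pediatric_prob = 0.05,
    n_departments = 20L,
    confirmation_delay_mean_days = 14.58,
    confirmation_delay_sd_days = 4.64,
    seed = 20121001L
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) {
      abort_habsi(paste0("unknown cohort configuration field(s): ",
                         paste(bad, collapse = ", ")))
    }
    cfg[names(overrides)] <- overrides
  }
  validate_cohort_config(cfg)
  structure(cfg, class = "habsi_cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || cfg$n_patients < 1) {
    abort_habsi("n_patients must be a positive integer")
  }
  period <- parse_date(cfg$period)
  if (length(period) != 2 || any(is.na(period)) ||
      as.numeric(period[2] - period[1]) < 6) {
    abort_habsi("period must span at least 7 days")
  }
  if (cfg$habsi_rate_per_1000_patients < 0 ||
      cfg$habsi_rate_per_1000_patients > 1000) {
    abort_habsi("infeasible habsi_rate_per_1000_patients: more cases than patients")
  }
  probs <- c("contamination_prob", "single_draw_prob", "commensal_single_draw_prob",
             "revision_after_recall_prob", "inwindow_revision_prob", "readmit_prob",
             "commensal_case_prob", "community_onset_prob", "fever_only_prob",
             "abx_only_prob", "persistent_repeat_prob", "pediatric_prob")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) abort_habsi(paste0(p, " must be in [0, 1]"))
  }
  mix <- cfg$subtype_mix
  if (!setequal(names(mix), CLASSIFICATIONS) || any(mix < 0) ||
      abs(sum(mix) - 1) > 1e-8) {
    abort_habsi("subtype_mix must be probabilities over the five classes summing to 1")
  }
  invisible(cfg)
}

SIM_PATHOGENS <- c("Escherichia coli", "Klebsiella pneumoniae", "Staphylococcus aureus",
                   "Pseudomonas aeruginosa", "Enterococcus faecalis",
                   "Acinetobacter baumannii", "Candida albicans", "Enterobacter cloacae")
SIM_PATHOGEN_W <- c(0.24, 0.18, 0.16, 0.12, 0.10, 0.08, 0.07, 0.05)
SIM_COMMENSALS <- c("Staphylococcus epidermidis", "Staphylococcus hominis",
                    "Micrococcus luteus", "Corynebacterium striatum",
                    "Cutibacterium acnes", "Streptococcus mitis")

#' Generate a ground-truth-labeled synthetic EMR cohort
#'
#' Seeded and reproducible: the same configuration (including `seed`)
#' yields byte-identical output streams. See [cohort_config] for what is
#' planted and why.
#'
#' @param config a [cohort_config()].
#' @return an object of class `habsi_cohort`: list with `bundle` (a
#'   [habsi_bundle]), `truth` (tibble `patient_id`, `department`, `habsi`,
#'   `classification`, `onset_ts`, `confirmation_ts`) and `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 200, seed = 7))
#' cohort$bundle
#' sum(cohort$truth$habsi)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "habsi_cohort_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- as.integer(config$n_patients)
  ps <- parse_date(config$period)[1]
  pe <- parse_date(config$period)[2]
  pid <- sprintf("P%05d", seq_len(n))
  pediatric <- stats::runif(n) < config$pediatric_prob
  birth <- ifelse(pediatric,
                  as.character(ps - sample(30:300, n, replace = TRUE)),
                  as.character(ps - sample(6570:32850, n, replace = TRUE)))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  dept_w <- seq(2, 0.4, length.out = config$n_departments)
  dept <- sample(sprintf("D%02d", seq_len(config$n_departments)), n,
                 replace = TRUE, prob = dept_w / sum(dept_w))

  is_case <- stats::runif(n) < config$habsi_rate_per_1000_patients / 1000
  subtype <- rep(NA_character_, n)
  subtype[is_case] <- sample(names(config$subtype_mix), sum(is_case),
                             replace = TRUE, prob = config$subtype_mix)
  role <- rep("none", n)
  neg <- which(!is_case)
  role_p <- c(community = config$community_onset_prob,
              contaminant = config$contamination_prob,
              rev_fp = config$revision_after_recall_prob,
              rev_ok = config$inwindow_revision_prob,
              fever_only = config$fever_only_prob,
              abx_only = config$abx_only_prob)
  role_p <- c(role_p, none = max(0, 1 - sum(role_p)))
  role[neg] <- sample(names(role_p), length(neg), replace = TRUE, prob = role_p)

  # admission and length of stay, vectorized; case timing derived so the
  # onset always fits the surveillance period
  adm_date <- ps + sample.int(as.numeric(pe - ps) - 1, n, replace = TRUE) - 3L
  adm_date[is_case] <- pmin(pmax(adm_date[is_case], ps), pe - 5)
  adm_min <- sample.int(24 * 60, n, replace = TRUE) - 1L
  los_days <- pmin(30, 1 + round(stats::rgamma(n, shape = 2, scale = 3.5), 2))
  needs_long <- role %in% c("contaminant", "rev_fp", "rev_ok", "fever_only", "abx_only")
  los_days[needs_long] <- pmax(los_days[needs_long], 7)
  readmit <- stats::runif(n) < config$readmit_prob
  case_readmit <- is_case & readmit & adm_date <= pe - 9

  adm <- ts_from_date(adm_date, minutes = adm_min)
  gap1 <- sample(1:2, n, replace = TRUE)    # linked re-admission gap (cases)
  gap2 <- sample(1:8, n, replace = TRUE)    # mixed gaps (non-cases)
  onset_u <- stats::runif(n)
  case_los <- 3 + stats::rgamma(n, 2, scale = 1.5)

  # onset: >= 48 h after first admission; for linked re-admissions the
  # onset sits early in the second stay so detection depends on linkage
  onset_vec <- trunc_minute(adm + (48 + onset_u * 72) * 3600)
  adm2_case <- adm + (3 + gap1) * 86400
  onset_vec[case_readmit] <- trunc_minute(adm2_case + (2 + onset_u * 28) * 3600)[case_readmit]

  dis1 <- trunc_minute(adm + los_days * 86400)
  dis1[is_case & !case_readmit] <-
    trunc_minute(onset_vec + case_los * 86400)[is_case & !case_readmit]
  dis1[case_readmit] <- (adm + 3 * 86400)[case_readmit]
  adm2 <- trunc_minute(dis1 + gap2 * 86400)
  adm2[case_readmit] <- adm2_case[case_readmit]
  dis2 <- trunc_minute(adm2 + stats::runif(n, 2, 6) * 86400)
  dis2[case_readmit] <- trunc_minute(onset_vec + case_los * 86400)[case_readmit]
  has_stay2 <- readmit & (!is_case | case_readmit)

  one <- tibble::tibble(
    patient_id = pid, stay_id = paste0(pid, "-S1"),
    admission_ts = fmt_ts(adm), discharge_ts = fmt_ts(dis1),
    birth_date = birth, sex = sex,
    transfers = paste0(dept, SEP_KV, fmt_ts(adm)))
  two <- tibble::tibble(
    patient_id = pid[has_stay2], stay_id = paste0(pid[has_stay2], "-S2"),
    admission_ts = fmt_ts(adm2[has_stay2]), discharge_ts = fmt_ts(dis2[has_stay2]),
    birth_date = birth[has_stay2], sex = sex[has_stay2],
    transfers = paste0(dept[has_stay2], SEP_KV, fmt_ts(adm2[has_stay2])))
  stays_tbl <- dplyr::bind_rows(one, two)
  stays_tbl <- stays_tbl[order(stays_tbl$patient_id, stays_tbl$stay_id), ]

  cultures <- vector("list", n)
  vitals_extra <- vector("list", n)
  devices <- vector("list", n)
  abx <- vector("list", n)
  truth_class <- rep(NA_character_, n)
  truth_onset <- rep(NA_real_, n)

  spec_counter <- 0L
  next_spec <- function(k = 1L) {
    ids <- sprintf("S%06d", spec_counter + seq_len(k))
    spec_counter <<- spec_counter + k
    ids
  }
  culture_row <- function(patient, login, type, orgs, revisions = NULL) {
    tibble::tibble(specimen_id = next_spec(), patient_id = patient,
                   login_ts = login, specimen_type = type,
                   organisms = list(orgs), report_final_ts = login + 48 * 3600,
                   revisions = list(revisions %||% empty_revisions()))
  }
  fever_rows <- function(patient, around) {
    tibble::tibble(patient_id = patient,
                   ts = c(around - 2 * 3600, around + 4 * 3600),
                   temperature_c = round(stats::runif(2, 38.4, 39.6), 1),
                   heart_rate_bpm = round(stats::runif(2, 95, 120)),
                   respiratory_rate_pm = round(stats::runif(2, 22, 28)))
  }

  for (i in which(is_case | role != "none")) {
    adm_i <- adm[i]

    if (is_case[i]) {
      onset <- onset_vec[i]
      dis <- if (case_readmit[i]) dis2[i] else dis1[i]
      truth_onset[i] <- as.numeric(onset)
      truth_class[i] <- subtype[i]
      st <- subtype[i]

      if (st == "CSEP") {
        vitals_extra[[i]] <- fever_rows(pid[i], onset)
        abx[[i]] <- tibble::tibble(patient_id = pid[i], drug_code = "J01DH02",
                                   start_ts = onset + 6 * 3600,
                                   end_ts = onset + 7 * 86400)
        # sepsis work-up draws that stay negative
        cultures[[i]] <- culture_row(pid[i], onset + 1 * 3600, "blood", character(0))
      } else {
        commensal_case <- st != "SEC" &&
          stats::runif(1) < config$commensal_case_prob
        org <- if (commensal_case) sample(SIM_COMMENSALS, 1)
               else sample(SIM_PATHOGENS, 1, prob = SIM_PATHOGEN_W)
        two_draws <- if (commensal_case) {
          stats::runif(1) >= config$commensal_single_draw_prob
        } else {
          stats::runif(1) >= config$single_draw_prob
        }
        cu <- culture_row(pid[i], onset, "blood", org)
        if (two_draws) {
          cu <- dplyr::bind_rows(cu, culture_row(pid[i], onset + 50 * 60, "blood", org))
        }
        if (stats::runif(1) < config$persistent_repeat_prob) {
          rep_ts <- trunc_minute(onset + stats::runif(1, 4, 10) * 86400)
          if (rep_ts < dis - 12 * 3600) {
            cu <- dplyr::bind_rows(cu, culture_row(pid[i], rep_ts, "blood", org))
          }
        }
        vitals_extra[[i]] <- fever_rows(pid[i], onset)
        abx_start <- if (commensal_case) onset + 60 * 3600 else onset + 4 * 3600
        abx[[i]] <- tibble::tibble(patient_id = pid[i], drug_code = "J01GB03",
                                   start_ts = abx_start, end_ts = abx_start + 7 * 86400)
        if (st %in% c("PRIM_CRBSI", "PRIM_CLABSI")) {
          devices[[i]] <- tibble::tibble(patient_id = pid[i],
                                         device_type = "central_line",
                                         start_ts = adm_i + 2 * 3600,
                                         end_ts = onset + 2 * 86400)
        } else if (st == "PRIM_OTHER" && stats::runif(1) < 0.5) {
          devices[[i]] <- tibble::tibble(patient_id = pid[i],
                                         device_type = "urinary_catheter",
                                         start_ts = adm_i + 2 * 3600,
                                         end_ts = onset + 2 * 86400)
        }
        if (st == "PRIM_CRBSI") {
          cu <- dplyr::bind_rows(cu, culture_row(pid[i], onset + 86400,
                                                 "catheter_tip", org))
        }
        if (st == "SEC") {
          site <- sample(c("urine", "sputum", "wound"), 1)
          site_ts <- trunc_minute(onset - stats::runif(1, 0, 2) * 86400)
          cu <- dplyr::bind_rows(cu, culture_row(pid[i], site_ts, site, org))
        }
        cultures[[i]] <- cu
      }
    } else {
      dis <- dis1[i]
      r <- role[i]
      if (r == "community") {
        # positive draws before the 48-hour mark: community onset, not HABSI
        t0 <- trunc_minute(adm_i + stats::runif(1, 2, 40) * 3600)
        org <- sample(SIM_PATHOGENS, 1, prob = SIM_PATHOGEN_W)
        cultures[[i]] <- dplyr::bind_rows(
          culture_row(pid[i], t0, "blood", org),
          culture_row(pid[i], t0 + 50 * 60, "blood", org))
        vitals_extra[[i]] <- fever_rows(pid[i], t0)
        abx[[i]] <- tibble::tibble(patient_id = pid[i], drug_code = "J01CR05",
                                   start_ts = t0 + 4 * 3600, end_ts = t0 + 7 * 86400)
      } else if (r %in% c("contaminant", "rev_fp", "rev_ok", "fever_only", "abx_only")) {
        t0 <- trunc_minute(adm_i + stats::runif(1, 50, 120) * 3600)
        if (t0 > dis - 6 * 3600) t0 <- dis - 6 * 3600
        if (r == "contaminant") {
          cultures[[i]] <- culture_row(pid[i], t0, "blood", sample(SIM_COMMENSALS, 1))
          if (stats::runif(1) < 0.5) vitals_extra[[i]] <- fever_rows(pid[i], t0)
        } else if (r %in% c("rev_fp", "rev_ok")) {
          # final report shows a pathogen; the correction to a commensal
          # contaminant arrives after (rev_fp) or inside (rev_ok) the
          # recall window
          final_ts <- t0 + 48 * 3600
          rev_delay_days <- if (r == "rev_fp") 10 else 2
          rev <- tibble::tibble(
            revision_ts = final_ts + rev_delay_days * 86400,
            organisms = list(sample(SIM_COMMENSALS, 1)))
          cultures[[i]] <- culture_row(pid[i], t0, "blood",
                                       sample(SIM_PATHOGENS, 1, prob = SIM_PATHOGEN_W),
                                       revisions = rev)
        } else if (r == "fever_only") {
          vitals_extra[[i]] <- fever_rows(pid[i], t0)
        } else {
          abx[[i]] <- tibble::tibble(patient_id = pid[i], drug_code = "J01MA02",
                                     start_ts = t0, end_ts = t0 + 5 * 86400)
        }
      }
    }
  }

  # routine daily vitals for every stay day
  adm_all <- parse_ts(stays_tbl$admission_ts)
  dis_all <- parse_ts(stays_tbl$discharge_ts)
  n_days <- as.integer(pmax(1, as.numeric(as.Date(fmt_ts(dis_all)) -
                                            as.Date(fmt_ts(adm_all))) + 1))
  base_pid <- rep(stays_tbl$patient_id, n_days)
  base_day <- as.Date(fmt_ts(rep(adm_all, n_days))) +
    (sequence(n_days) - 1)
  base_ped <- rep(pediatric[match(stays_tbl$patient_id, pid)], n_days)
  m <- length(base_pid)
  baseline <- tibble::tibble(
    patient_id = base_pid,
    ts = ts_from_date(base_day, hours = 8),
    temperature_c = round(stats::runif(m, 36.4, 37.4), 1),
    heart_rate_bpm = round(ifelse(base_ped, stats::runif(m, 110, 150),
                                  stats::runif(m, 65, 88))),
    respiratory_rate_pm = round(ifelse(base_ped, stats::runif(m, 25, 40),
                                       stats::runif(m, 12, 19)))
  )

  bundle <- habsi_bundle(
    stays = stays_tbl,
    cultures = dplyr::bind_rows(cultures),
    vitals = dplyr::bind_rows(baseline, dplyr::bind_rows(vitals_extra)),
    devices = dplyr::bind_rows(devices),
    abx = dplyr::bind_rows(abx)
  )

  delay_mean <- config$confirmation_delay_mean_days
  delay_sd <- config$confirmation_delay_sd_days
  shape <- (delay_mean / delay_sd)^2
  delay <- stats::rgamma(n, shape = shape, rate = shape / delay_mean)
  onset_ts <- trunc_minute(as.POSIXct(truth_onset, origin = "1970-01-01", tz = HABSI_TZ))
  truth <- tibble::tibble(
    patient_id = pid, department = dept, habsi = is_case,
    classification = truth_class, onset_ts = onset_ts,
    confirmation_ts = trunc_minute(onset_ts + delay * 86400)
  )
  truth$confirmation_ts[!is_case] <- parse_ts(NA)

  structure(list(bundle = bundle, truth = truth, config = config),
            class = "habsi_cohort")
}

#' @export
print.habsi_cohort <- function(x, ...) {
  cat("<habsi_cohort> ", x$config$n_patients, " patients, ",
      sum(x$truth$habsi), " planted HABSI cases (seed ", x$config$seed, ")\n",
      sep = "")
  print(x$bundle)
  invisible(x)
}

#' Write a synthetic cohort to an output directory
#'
#' Writes the five EMR streams via [write_tables()] plus
#' `reference_labels.csv` with the ground truth.
#'
#' @param cohort a `habsi_cohort` from [generate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "habsi_cohort"))
  write_tables(cohort$bundle, dir)
  tr <- cohort$truth
  tr$habsi <- as.integer(tr$habsi)
  tr$onset_ts <- fmt_ts(tr$onset_ts)
  tr$confirmation_ts <- fmt_ts(tr$confirmation_ts)
  readr::write_csv(tr, file.path(dir, "reference_labels.csv"), progress = FALSE)
  invisible(dir)
}
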