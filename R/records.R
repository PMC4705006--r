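#' Domain record streams
#'
#' The engine works on five typed EMR streams plus an optional reference
#' label stream, each a tibble with a fixed schema:
#'
#' * `stays`: `patient_id`, `stay_id`, `admission_ts`, `discharge_ts`
#'   (NA = still admitted), `birth_date`, `sex` (`F`/`M`/`U`), `transfers`
#'   (list-column of tibbles with `ward_id`, `enter_ts`; the first transfer
#'   starts at admission).
#' * `cultures`: `specimen_id`, `patient_id`, `login_ts` (laboratory
#'   log-in, used as the collection-time and onset proxy), `specimen_type`
#'   (`blood`, `catheter_tip`, `urine`, `sputum`, `wound`, `csf`, `other`),
#'   `organisms` (list-column of `Genus species` character vectors; empty =
#'   no growth), `report_final_ts`, `revisions` (list-column of tibbles
#'   with `revision_ts`, `organisms`; each revision replaces the organism
#'   set).
#' * `vitals`: `patient_id`, `ts`, `temperature_c`, `heart_rate_bpm`,
#'   `respiratory_rate_pm` (at least one present per row).
#' * `devices`: `patient_id`, `device_type` (`central_line`,
#'   `urinary_catheter`, `ventilator`, `other`), `start_ts`, `end_ts`
#'   (NA = still in place).
#' * `abx`: `patient_id`, `drug_code`, `start_ts`, `end_ts`.
#'
#' `habsi_bundle()` collects the five streams (validating each); the
#' validators return the accepted rows and a `rejected` attribute holding
#' the offending input rows with a `reason` column, so that
#' `accepted + rejected == input` always holds.
#'
#' @param stays,cultures,vitals,devices,abx stream tibbles/data frames.
#' @return `habsi_bundle()` returns a classed list with the five validated
#'   streams.
#' @name records
NULL

SPECIMEN_TYPES <- c("blood", "catheter_tip", "urine", "sputum", "wound", "csf", "other")
DEVICE_TYPES <- c("central_line", "urinary_catheter", "ventilator", "other")
SEX_LEVELS <- c("F", "M", "U")
CLASSIFICATIONS <- c("PRIM_CRBSI", "PRIM_CLABSI", "PRIM_OTHER", "SEC", "CSEP")

empty_transfers <- function() {
  tibble::tibble(ward_id = character(0), enter_ts = parse_ts(character(0)))
}

empty_revisions <- function() {
  tibble::tibble(revision_ts = parse_ts(character(0)), organisms = list())
}

finish_validation <- function(input, accepted, reason) {
  rejected <- input[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  attr(accepted, "rejected") <- tibble::as_tibble(rejected)
  accepted
}

#' @rdname records
#' @export
validate_stays <- function(stays) {
  stays <- tibble::as_tibble(stays)
  need <- c("patient_id", "stay_id", "admission_ts", "discharge_ts", "birth_date", "sex")
  missing <- setdiff(need, names(stays))
  if (length(missing)) {
    abort_habsi(paste0("stays: missing column(s): ", paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    patient_id = as.character(stays$patient_id),
    stay_id = as.character(stays$stay_id),
    admission_ts = parse_ts(stays$admission_ts),
    discharge_ts = parse_ts(stays$discharge_ts),
    birth_date = parse_date(stays$birth_date),
    sex = as.character(stays$sex)
  )
  if ("transfers" %in% names(stays) && is.list(stays$transfers)) {
    out$transfers <- stays$transfers
  } else if ("transfers" %in% names(stays)) {
    out$transfers <- decode_transfers(stays$transfers)
  } else {
    out$transfers <- replicate(nrow(out), NULL, simplify = FALSE)
  }
  # default transfer history: one ward entry at admission
  out$transfers <- purrr::pmap(
    list(out$transfers, out$admission_ts),
    function(tr, adm) {
      if (is.null(tr) || !nrow(tr)) {
        tibble::tibble(ward_id = "W00", enter_ts = adm)
      } else {
        tr <- tibble::as_tibble(tr)
        tr$enter_ts <- parse_ts(tr$enter_ts)
        tr[order(tr$enter_ts), ]
      }
    }
  )
  reason <- rep(NA_character_, nrow(out))
  bad_id <- is.na(out$patient_id) | out$patient_id == "" | is.na(out$stay_id) | out$stay_id == ""
  reason[is.na(reason) & bad_id] <- "missing patient_id or stay_id"
  reason[is.na(reason) & is.na(out$admission_ts)] <- "unparseable admission_ts"
  bad_order <- !is.na(out$discharge_ts) & out$discharge_ts <= out$admission_ts
  reason[is.na(reason) & bad_order] <- "discharge_ts not after admission_ts"
  reason[is.na(reason) & !(out$sex %in% SEX_LEVELS)] <- "sex not in {F,M,U}"
  bad_tr <- purrr::map2_lgl(out$transfers, out$admission_ts,
                            function(tr, adm) tr$enter_ts[1] != adm)
  reason[is.na(reason) & bad_tr] <- "first transfer does not start at admission"
  finish_validation(stays, out[is.na(reason), ], reason)
}

#' @rdname records
#' @export
validate_cultures <- function(cultures) {
  cultures <- tibble::as_tibble(cultures)
  need <- c("specimen_id", "patient_id", "login_ts", "specimen_type",
            "organisms", "report_final_ts")
  missing <- setdiff(need, names(cultures))
  if (length(missing)) {
    abort_habsi(paste0("cultures: missing column(s): ", paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    specimen_id = as.character(cultures$specimen_id),
    patient_id = as.character(cultures$patient_id),
    login_ts = parse_ts(cultures$login_ts),
    specimen_type = as.character(cultures$specimen_type),
    organisms = if (is.list(cultures$organisms)) cultures$organisms
                else decode_orgs(cultures$organisms),
    report_final_ts = parse_ts(cultures$report_final_ts)
  )
  if ("revisions" %in% names(cultures) && is.list(cultures$revisions)) {
    out$revisions <- purrr::map(cultures$revisions, function(r) {
      if (is.null(r)) empty_revisions() else tibble::as_tibble(r)
    })
  } else if ("revisions" %in% names(cultures)) {
    out$revisions <- decode_revisions(cultures$revisions)
  } else {
    out$revisions <- replicate(nrow(out), empty_revisions(), simplify = FALSE)
  }
  reason <- rep(NA_character_, nrow(out))
  bad_id <- is.na(out$specimen_id) | out$specimen_id == "" |
    is.na(out$patient_id) | out$patient_id == ""
  reason[is.na(reason) & bad_id] <- "missing specimen_id or patient_id"
  reason[is.na(reason) & is.na(out$login_ts)] <- "unparseable login_ts"
  reason[is.na(reason) & !(out$specimen_type %in% SPECIMEN_TYPES)] <-
    "unknown specimen_type"
  bad_final <- is.na(out$report_final_ts) | out$report_final_ts < out$login_ts
  reason[is.na(reason) & bad_final] <- "report_final_ts before login_ts"
  bad_rev <- purrr::map_lgl(out$revisions, function(r) {
    nrow(r) > 1 && any(diff(as.numeric(r$revision_ts)) <= 0)
  })
  reason[is.na(reason) & bad_rev] <- "revision_ts not strictly increasing"
  finish_validation(cultures, out[is.na(reason), ], reason)
}

#' @rdname records
#' @export
validate_vitals <- function(vitals) {
  vitals <- tibble::as_tibble(vitals)
  need <- c("patient_id", "ts", "temperature_c", "heart_rate_bpm", "respiratory_rate_pm")
  missing <- setdiff(need, names(vitals))
  if (length(missing)) {
    abort_habsi(paste0("vitals: missing column(s): ", paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    patient_id = as.character(vitals$patient_id),
    ts = parse_ts(vitals$ts),
    temperature_c = as.numeric(vitals$temperature_c),
    heart_rate_bpm = as.numeric(vitals$heart_rate_bpm),
    respiratory_rate_pm = as.numeric(vitals$respiratory_rate_pm)
  )
  # plausibility bounds: implausible measurements are blanked with a warning
  bad_t <- !is.na(out$temperature_c) & (out$temperature_c < 30 | out$temperature_c > 45)
  bad_h <- !is.na(out$heart_rate_bpm) & (out$heart_rate_bpm < 0 | out$heart_rate_bpm > 350)
  bad_r <- !is.na(out$respiratory_rate_pm) &
    (out$respiratory_rate_pm < 0 | out$respiratory_rate_pm > 150)
  n_bad <- sum(bad_t) + sum(bad_h) + sum(bad_r)
  if (n_bad > 0) {
    warning(sprintf("vitals: %d implausible measurement(s) set to missing", n_bad),
            call. = FALSE)
    out$temperature_c[bad_t] <- NA_real_
    out$heart_rate_bpm[bad_h] <- NA_real_
    out$respiratory_rate_pm[bad_r] <- NA_real_
  }
  reason <- rep(NA_character_, nrow(out))
  reason[is.na(reason) & (is.na(out$patient_id) | out$patient_id == "")] <-
    "missing patient_id"
  reason[is.na(reason) & is.na(out$ts)] <- "unparseable ts"
  none <- is.na(out$temperature_c) & is.na(out$heart_rate_bpm) &
    is.na(out$respiratory_rate_pm)
  reason[is.na(reason) & none] <- "no measurement present"
  finish_validation(vitals, out[is.na(reason), ], reason)
}

validate_interval_stream <- function(x, type_col, type_levels, stream) {
  x <- tibble::as_tibble(x)
  need <- c("patient_id", type_col, "start_ts", "end_ts")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort_habsi(paste0(stream, ": missing column(s): ", paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    patient_id = as.character(x$patient_id),
    start_ts = parse_ts(x$start_ts),
    end_ts = parse_ts(x$end_ts)
  )
  out[[type_col]] <- as.character(x[[type_col]])
  out <- out[, c("patient_id", type_col, "start_ts", "end_ts")]
  reason <- rep(NA_character_, nrow(out))
  reason[is.na(reason) & (is.na(out$patient_id) | out$patient_id == "")] <-
    "missing patient_id"
  reason[is.na(reason) & is.na(out$start_ts)] <- "unparseable start_ts"
  if (!is.null(type_levels)) {
    reason[is.na(reason) & !(out[[type_col]] %in% type_levels)] <-
      paste0("unknown ", type_col)
  }
  bad <- !is.na(out$end_ts) & out$end_ts <= out$start_ts
  reason[is.na(reason) & bad] <- "end_ts not after start_ts"
  finish_validation(x, out[is.na(reason), ], reason)
}

#' @rdname records
#' @export
validate_devices <- function(devices) {
  validate_interval_stream(devices, "device_type", DEVICE_TYPES, "devices")
}

#' @rdname records
#' @export
validate_abx <- function(abx) {
  validate_interval_stream(abx, "drug_code", NULL, "abx")
}

#' @rdname records
#' @export
habsi_bundle <- function(stays, cultures = NULL, vitals = NULL,
                         devices = NULL, abx = NULL) {
  b <- list(
    stays = validate_stays(stays),
    cultures = if (is.null(cultures)) empty_cultures() else validate_cultures(cultures),
    vitals = if (is.null(vitals)) empty_vitals() else validate_vitals(vitals),
    devices = if (is.null(devices)) empty_devices() else validate_devices(devices),
    abx = if (is.null(abx)) empty_abx() else validate_abx(abx)
  )
  structure(b, class = "habsi_bundle")
}

empty_cultures <- function() {
  tibble::tibble(specimen_id = character(0), patient_id = character(0),
                 login_ts = parse_ts(character(0)), specimen_type = character(0),
                 organisms = list(), report_final_ts = parse_ts(character(0)),
                 revisions = list())
}

empty_vitals <- function() {
  tibble::tibble(patient_id = character(0), ts = parse_ts(character(0)),
                 temperature_c = numeric(0), heart_rate_bpm = numeric(0),
                 respiratory_rate_pm = numeric(0))
}

empty_devices <- function() {
  tibble::tibble(patient_id = character(0), device_type = character(0),
                 start_ts = parse_ts(character(0)), end_ts = parse_ts(character(0)))
}

empty_abx <- function() {
  tibble::tibble(patient_id = character(0), drug_code = character(0),
                 start_ts = parse_ts(character(0)), end_ts = parse_ts(character(0)))
}

#' @export
print.habsi_bundle <- function(x, ...) {
  cat("<habsi_bundle>\n")
  cat(sprintf("  stays:    %6d rows (%d patients)\n", nrow(x$stays),
              dplyr::n_distinct(x$stays$patient_id)))
  cat(sprintf("  cultures: %6d rows (%d blood)\n", nrow(x$cultures),
              sum(x$cultures$specimen_type == "blood")))
  cat(sprintf("  vitals:   %6d rows\n", nrow(x$vitals)))
  cat(sprintf("  devices:  %6d rows\n", nrow(x$devices)))
  cat(sprintf("  abx:      %6d rows\n", nrow(x$abx)))
  invisible(x)
}

# --- encoders for nested CSV fields ---------------------------------------

encode_transfers <- function(transfers) {
  vapply(transfers, function(tr) {
    if (is.null(tr) || !nrow(tr)) return("")
    paste(paste0(tr$ward_id, SEP_KV, fmt_ts(tr$enter_ts)), collapse = SEP_REC)
  }, character(1))
}

decode_transfers <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || s == "") return(NULL)
    parts <- strsplit(s, SEP_REC, fixed = TRUE)[[1]]
    kv <- strsplit(parts, SEP_KV, fixed = TRUE)
    tibble::tibble(
      ward_id = vapply(kv, `[`, character(1), 1),
      enter_ts = parse_ts(vapply(kv, `[`, character(1), 2))
    )
  })
}

encode_revisions <- function(revisions) {
  vapply(revisions, function(r) {
    if (is.null(r) || !nrow(r)) return("")
    paste(paste0(fmt_ts(r$revision_ts), SEP_KV, encode_orgs(r$organisms)),
          collapse = SEP_REC)
  }, character(1))
}

decode_revisions <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || s == "") return(empty_revisions())
    parts <- strsplit(s, SEP_REC, fixed = TRUE)[[1]]
    kv <- strsplit(parts, SEP_KV, fixed = TRUE)
    tibble::tibble(
      revision_ts = parse_ts(vapply(kv, `[`, character(1), 1)),
      organisms = decode_orgs(vapply(kv, function(p) {
        if (length(p) >= 2) p[[2]] else ""
      }, character(1)))
    )
  })
}
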