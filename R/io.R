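#' Read EMR extract tables into a validated bundle
#'
#' Reads the flat-table interchange files (one CSV per stream) documented
#' in [records]. Nested fields are flat-encoded: organism sets with `|`
#' between organisms; ward transfers as `ward~timestamp` entries separated
#' by `;`; report revisions as `timestamp~org|org` entries separated by
#' `;`. Timestamps are ISO-8601 (`YYYY-MM-DDTHH:MM`) on a single implicit
#' timezone-naive minute grid.
#'
#' Rows that violate a record invariant (e.g. discharge before admission)
#' are rejected with a row-level diagnostic rather than silently dropped:
#' the per-stream `rejected` attribute holds the offending input rows and
#' reasons, and a summary message reports counts. A missing required column
#' is a fatal schema error.
#'
#' @param dir directory containing `stays.csv` and optionally
#'   `cultures.csv`, `vitals.csv`, `devices.csv`, `abx.csv`.
#' @param quiet suppress the ingest summary message.
#' @return a [habsi_bundle].
#' @export
read_tables <- function(dir, quiet = FALSE) {
  if (!dir.exists(dir)) abort_habsi(paste0("input directory not found: ", dir))
  path <- function(f) file.path(dir, f)
  if (!file.exists(path("stays.csv"))) {
    abort_habsi("stays.csv is required but was not found")
  }
  read1 <- function(f) {
    if (!file.exists(path(f))) return(NULL)
    readr::read_csv(path(f), col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
  bundle <- habsi_bundle(
    stays = read1("stays.csv"),
    cultures = read1("cultures.csv"),
    vitals = read1("vitals.csv"),
    devices = read1("devices.csv"),
    abx = read1("abx.csv")
  )
  if (!quiet) {
    for (s in names(bundle)) {
      rej <- attr(bundle[[s]], "rejected")
      if (!is.null(rej) && nrow(rej)) {
        message(sprintf("%s: rejected %d row(s); first reason: %s",
                        s, nrow(rej), rej$reason[1]))
      }
    }
  }
  bundle
}

#' @rdname read_tables
#' @param bundle a [habsi_bundle].
#' @param dir output directory (created if absent).
#' @return `write_tables()` returns `dir` invisibly.
#' @export
write_tables <- function(bundle, dir) {
  stopifnot(inherits(bundle, "habsi_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  st <- bundle$stays
  st$transfers <- encode_transfers(st$transfers)
  st$admission_ts <- fmt_ts(st$admission_ts)
  st$discharge_ts <- fmt_ts(st$discharge_ts)
  st$birth_date <- as.character(st$birth_date)
  readr::write_csv(st, file.path(dir, "stays.csv"), progress = FALSE)
  cu <- bundle$cultures
  cu$organisms <- encode_orgs(cu$organisms)
  cu$revisions <- encode_revisions(cu$revisions)
  cu$login_ts <- fmt_ts(cu$login_ts)
  cu$report_final_ts <- fmt_ts(cu$report_final_ts)
  readr::write_csv(cu, file.path(dir, "cultures.csv"), progress = FALSE)
  vi <- bundle$vitals
  vi$ts <- fmt_ts(vi$ts)
  readr::write_csv(vi, file.path(dir, "vitals.csv"), progress = FALSE)
  de <- bundle$devices
  de$start_ts <- fmt_ts(de$start_ts)
  de$end_ts <- fmt_ts(de$end_ts)
  readr::write_csv(de, file.path(dir, "devices.csv"), progress = FALSE)
  ab <- bundle$abx
  ab$start_ts <- fmt_ts(ab$start_ts)
  ab$end_ts <- fmt_ts(ab$end_ts)
  readr::write_csv(ab, file.path(dir, "abx.csv"), progress = FALSE)
  invisible(dir)
}

#' Write / read a deterministic HABSI event line list
#'
#' Events are written with a fixed column order and sorted by `onset_ts`,
#' then `patient_id`, then `event_id`, so repeated runs over the same data
#' are byte-identical. `read_line_list()` restores the typed tibble,
#' including the organism and source-specimen list-columns.
#'
#' @param events an event tibble as returned by [run_pipeline()].
#' @param path output CSV path.
#' @return `write_line_list()` returns `path` invisibly;
#'   `read_line_list()` returns the event tibble.
#' @export
write_line_list <- function(events, path) {
  ev <- tibble::as_tibble(events)
  ev <- ev[order(ev$onset_ts, ev$patient_id, ev$event_id), ]
  out <- tibble::tibble(
    event_id = ev$event_id,
    patient_id = ev$patient_id,
    episode_id = ev$episode_id,
    onset_ts = fmt_ts(ev$onset_ts),
    classification = ev$classification,
    organisms = encode_orgs(ev$organisms),
    source_specimens = encode_orgs(ev$source_specimens),
    confirmation_ts = fmt_ts(ev$confirmation_ts),
    n_candidates = ev$n_candidates
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_line_list
#' @export
read_line_list <- function(path) {
  if (!file.exists(path)) abort_habsi(paste0("event file not found: ", path))
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  tibble::tibble(
    event_id = x$event_id,
    patient_id = x$patient_id,
    episode_id = x$episode_id,
    onset_ts = parse_ts(x$onset_ts),
    classification = x$classification,
    organisms = decode_orgs(x$organisms),
    source_specimens = decode_orgs(x$source_specimens),
    confirmation_ts = parse_ts(x$confirmation_ts),
    n_candidates = as.integer(x$n_candidates)
  )
}

#' Read a reference-standard label file
#'
#' @param path CSV with columns `patient_id`, `habsi` (0/1 or TRUE/FALSE)
#'   and optionally `classification`, `onset_ts`, `confirmation_ts`.
#' @return a tibble of labels.
#' @export
read_reference_labels <- function(path) {
  if (!file.exists(path)) abort_habsi(paste0("reference label file not found: ", path))
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  need <- c("patient_id", "habsi")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort_habsi(paste0("reference_labels: missing column(s): ",
                       paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    patient_id = as.character(x$patient_id),
    habsi = as.character(x$habsi) %in% c("1", "TRUE", "true", "T")
  )
  if ("classification" %in% names(x)) out$classification <- as.character(x$classification)
  if ("onset_ts" %in% names(x)) out$onset_ts <- parse_ts(x$onset_ts)
  if ("confirmation_ts" %in% names(x)) out$confirmation_ts <- parse_ts(x$confirmation_ts)
  out
}
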