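#' Surveillance rule configuration
#'
#' All rule thresholds live in one flat configuration object so that every
#' site-specific adaptation (hospital-acquired cut-off, fever definition,
#' commensal corroboration window, deduplication windows, recall window for
#' late laboratory revisions) is explicit and serializable to YAML.
#'
#' Key parameters (units in parentheses):
#' \describe{
#'   \item{readmit_gap_days}{re-admissions within this many calendar days of
#'     discharge are linked to the previous stay as one hospitalization
#'     episode (days, default 2, inclusive).}
#'   \item{min_hai_hours}{a blood specimen is healthcare-associated when its
#'     log-in time is at least this long after the first admission of the
#'     episode (hours, default 48, inclusive).}
#'   \item{fever_c}{fever is any temperature strictly above this value
#'     (degrees Celsius, default 38.0).}
#'   \item{hypothermia_c}{hypothermia is any temperature strictly below this
#'     value (degrees Celsius, default 36.0).}
#'   \item{adult_hr_max, adult_rr_max}{tachycardia / tachypnea thresholds,
#'     strictly above, for patients older than `pediatric_age_max_days`.}
#'   \item{pediatric_age_max_days, pediatric_hr_max, pediatric_rr_max}{age
#'     band (days) and thresholds for neonates/infants.}
#'   \item{commensal_window_days}{a common skin commensal counts as a
#'     pathogen only when the same organism appears in two blood draws whose
#'     log-in dates are at most this many calendar days apart (default 2,
#'     mirroring the routine paired sets drawn 45-60 minutes apart).}
#'   \item{commensal_sign_window_hours}{at least one sign flag must be
#'     present within this window around the first corroborated draw
#'     (hours, default 24, i.e. +/- 24 h).}
#'   \item{recall_days}{laboratory report revisions are ingested only if
#'     they occur within this many days of the final report ("recall day");
#'     later revisions are deliberately ignored, reproducing a known
#'     false-positive mechanism of fixed-window LIS polling.}
#'   \item{csep_blood_window_hours, csep_abx_window_hours,
#'     csep_site_window_days}{clinical sepsis pathway: no confirmed positive
#'     blood culture within +/- 48 h of the sign, a new antimicrobial order
#'     within 48 h after the sign, no confirmed positive non-blood site
#'     culture within +/- 7 days.}
#'   \item{polymicrobial_hours}{candidates whose onsets fall within this
#'     window merge into one polymicrobial event (hours, default 48;
#'     0 disables the merge).}
#'   \item{persistent_days}{a candidate sharing an organism with an earlier
#'     event and with onset at most this many days after the event onset is
#'     absorbed as persistent bloodstream infection, not counted anew
#'     (days, default 14, non-extending; 0 disables).}
#'   \item{secondary_window_days}{a matching organism from a non-blood,
#'     non-catheter-tip site within +/- this many days of onset makes the
#'     event secondary (default 7).}
#'   \item{line_lookback_hours}{a central line overlapping
#'     `[onset - line_lookback_hours, onset]` makes a primary event
#'     line-associated (default 48).}
#'   \item{tip_window_days}{a concordant catheter-tip culture within +/-
#'     this many days of onset upgrades line-associated to catheter-related
#'     (default 7).}
#'   \item{commensal_species, commensal_genera, commensal_exclude}{the
#'     configured common-commensal list. An organism is a commensal iff its
#'     name is in `commensal_species`, or its genus is in `commensal_genera`
#'     and its name is not in `commensal_exclude`. Defaults cover
#'     coagulase-negative staphylococci, Micrococcus, Corynebacterium
#'     (non-diphtheriae), Bacillus (non-anthracis),
#'     Cutibacterium/Propionibacterium, viridans-group streptococci and
#'     Aerococcus.}
#' }
#'
#' @param ... named overrides of any default listed above.
#' @return an object of class `habsi_config` (a named list).
#' @examples
#' cfg <- habsi_config(fever_c = 38.3)
#' cfg$fever_c
#' @export
habsi_config <- function(...) {
  cfg <- list(
    readmit_gap_days = 2L,
    min_hai_hours = 48,
    fever_c = 38.0,
    hypothermia_c = 36.0,
    adult_hr_max = 90,
    adult_rr_max = 20,
    pediatric_age_max_days = 365,
    pediatric_hr_max = 180,
    pediatric_rr_max = 60,
    commensal_window_days = 2,
    commensal_sign_window_hours = 24,
    recall_days = 7,
    csep_blood_window_hours = 48,
    csep_abx_window_hours = 48,
    csep_site_window_days = 7,
    polymicrobial_hours = 48,
    persistent_days = 14,
    secondary_window_days = 7,
    line_lookback_hours = 48,
    tip_window_days = 7,
    commensal_species = c(
      "Streptococcus mitis", "Streptococcus oralis", "Streptococcus sanguinis",
      "Streptococcus salivarius", "Streptococcus mutans", "Streptococcus anginosus"
    ),
    commensal_genera = c(
      "Staphylococcus", "Micrococcus", "Corynebacterium", "Bacillus",
      "Cutibacterium", "Propionibacterium", "Aerococcus"
    ),
    commensal_exclude = c(
      "Staphylococcus aureus", "Staphylococcus lugdunensis",
      "Corynebacterium diphtheriae", "Bacillus anthracis"
    )
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) {
      abort_habsi(paste0("unknown configuration field(s): ", paste(bad, collapse = ", ")))
    }
    cfg[names(overrides)] <- overrides
  }
  validate_config(cfg)
  structure(cfg, class = "habsi_config")
}

validate_config <- function(cfg) {
  num_fields <- c(
    "readmit_gap_days", "min_hai_hours", "fever_c", "hypothermia_c",
    "adult_hr_max", "adult_rr_max", "pediatric_age_max_days",
    "pediatric_hr_max", "pediatric_rr_max", "commensal_window_days",
    "commensal_sign_window_hours", "recall_days", "csep_blood_window_hours",
    "csep_abx_window_hours", "csep_site_window_days", "polymicrobial_hours",
    "persistent_days", "secondary_window_days", "line_lookback_hours",
    "tip_window_days"
  )
  for (f in num_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      abort_habsi(paste0("configuration field '", f, "' must be a single number"))
    }
  }
  nonneg <- setdiff(num_fields, c("fever_c", "hypothermia_c"))
  for (f in nonneg) {
    if (cfg[[f]] < 0) abort_habsi(paste0("configuration field '", f, "' must be >= 0"))
  }
  invisible(cfg)
}

#' Read / write a configuration as YAML
#'
#' @param path file path.
#' @return `read_config()` returns a [habsi_config] object; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_habsi(paste0("configuration file not found: ", path))
  raw <- yaml::read_yaml(path)
  do.call(habsi_config, raw)
}

#' @rdname read_config
#' @param config a [habsi_config] object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "habsi_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.habsi_config <- function(x, ...) {
  cat("<habsi_config>\n")
  for (f in names(x)) {
    v <- x[[f]]
    cat("  ", f, ": ", paste(v, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Classify organism names as common skin commensals
#'
#' Membership in the configured commensal list is the sole criterion: an
#' organism is a commensal iff its normalized name is in
#' `commensal_species`, or its genus is in `commensal_genera` and the name
#' is not in `commensal_exclude`.
#'
#' @param organism character vector of `Genus species` names.
#' @param config a [habsi_config].
#' @return logical vector.
#' @examples
#' cfg <- habsi_config()
#' is_commensal(c("Staphylococcus epidermidis", "Staphylococcus aureus"), cfg)
#' @export
is_commensal <- function(organism, config = habsi_config()) {
  norm <- normalize_organism(organism)
  species <- normalize_organism(config$commensal_species)
  genera <- tolower(config$commensal_genera)
  excl <- normalize_organism(config$commensal_exclude)
  genus <- vapply(strsplit(norm, " ", fixed = TRUE),
                  function(p) if (length(p)) p[[1]] else "", character(1))
  (norm %in% species) | (genus %in% genera & !(norm %in% excl))
}

#' @rdname is_commensal
#' @export
normalize_organism <- function(organism) {
  x <- tolower(trimws(as.character(organism)))
  gsub("[[:space:]]+", " ", x)
}
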