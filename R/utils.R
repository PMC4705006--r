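# Internal helpers shared across modules.

# Timestamps live on a single timezone-naive minute grid; we represent them
# as POSIXct pinned to UTC and truncate to the minute at every ingest point.
HABSI_TZ <- "UTC"

parse_ts <- function(x) {
  if (inherits(x, "POSIXct")) {
    return(trunc_minute(x))
  }
  x <- as.character(x)
  x[x == ""] <- NA_character_
  # accept "YYYY-MM-DDTHH:MM[:SS]" and the space-separated variant
  y <- gsub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(y, tz = HABSI_TZ,
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  trunc_minute(out)
}

trunc_minute <- function(x) {
  as.POSIXct(floor(as.numeric(x) / 60) * 60, origin = "1970-01-01", tz = HABSI_TZ)
}

fmt_ts <- function(x) {
  out <- format(x, "%Y-%m-%dT%H:%M", tz = HABSI_TZ)
  out[is.na(x)] <- ""
  out
}

parse_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  x[x == ""] <- NA_character_
  as.Date(x)
}

ts_from_date <- function(d, hours = 0, minutes = 0) {
  trunc_minute(as.POSIXct(as.character(d), tz = HABSI_TZ) + hours * 3600 + minutes * 60)
}

hours_between <- function(from, to) as.numeric(difftime(to, from, units = "hours"))
days_between <- function(from, to) as.numeric(difftime(to, from, units = "days"))

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for display of percentages and
#' kappa, so that e.g. 98.155 prints as 98.16. Base `round()` rounds half
#' to even, which does not match how surveillance reports are formatted.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# separators for multi-valued CSV fields (documented in the I/O help page)
SEP_ORG <- "|"    # between organisms within one set
SEP_REC <- ";"    # between records (revisions, transfers)
SEP_KV  <- "~"    # between a timestamp/ward and its payload

encode_orgs <- function(orgs) {
  vapply(orgs, function(o) paste(o, collapse = SEP_ORG), character(1))
}

decode_orgs <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || s == "") character(0) else strsplit(s, SEP_ORG, fixed = TRUE)[[1]]
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_habsi <- function(msg, class = "habsi_error") {
  rlang::abort(msg, class = class)
}
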