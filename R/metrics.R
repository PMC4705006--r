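#' Patient-level confusion matrix against a reference standard
#'
#' Each patient in the evaluated population is counted exactly once; a
#' patient is "detected" iff at least one event is attributed to them, and
#' "reference positive" iff the reference standard labels them HABSI.
#'
#' @param events an event tibble (or any data frame with `patient_id`);
#'   alternatively a character vector of detected patient ids.
#' @param reference a tibble with `patient_id` and logical/0-1 `habsi`.
#' @param population character vector of every evaluated patient id.
#' @return an object of class `habsi_confusion`: list with integer `tp`,
#'   `fn`, `fp`, `tn`.
#' @export
patient_level_confusion <- function(events, reference, population) {
  detected <- if (is.character(events)) events else unique(events$patient_id)
  population <- unique(as.character(population))
  ref_pos <- unique(reference$patient_id[as.logical(reference$habsi)])
  unknown <- setdiff(unique(reference$patient_id), population)
  if (length(unknown)) {
    abort_habsi(paste0("reference label for patient(s) outside the population: ",
                       paste(utils::head(unknown, 3), collapse = ", ")),
                class = "habsi_data_error")
  }
  det <- population %in% detected
  pos <- population %in% ref_pos
  confusion_matrix(tp = sum(det & pos), fn = sum(!det & pos),
                   fp = sum(det & !pos), tn = sum(!det & !pos))
}

#' @rdname patient_level_confusion
#' @param tp,fn,fp,tn non-negative integer cell counts.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort_habsi("confusion-matrix cells must be non-negative integers")
  }
  structure(as.list(as.integer(cells)) |> stats::setNames(names(cells)),
            class = "habsi_confusion")
}

#' @export
print.habsi_confusion <- function(x, ...) {
  cat("<confusion> tp=", x$tp, " fn=", x$fn, " fp=", x$fp, " tn=", x$tn,
      " (N=", x$tp + x$fn + x$fp + x$tn, ")\n", sep = "")
  invisible(x)
}

clopper_pearson <- function(x, n, conf_level = 0.95) {
  a <- (1 - conf_level) / 2
  lower <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Diagnostic performance metrics from a confusion matrix
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), PPV tp/(tp+fp), NPV
#' tn/(tn+fn), each with an exact Clopper-Pearson confidence interval, and
#' Cohen's kappa `(p_o - p_e)/(1 - p_e)` with
#' `p_o = (tp+tn)/N` and
#' `p_e = ((tp+fn)(tp+fp) + (tn+fp)(tn+fn))/N^2`, with a large-sample
#' confidence interval from `SE = sqrt(p_o(1-p_o)/(N(1-p_e)^2))`.
#' A metric whose denominator is zero is flagged undefined (`NA` estimate
#' with `defined = FALSE`) rather than propagated as NaN.
#'
#' @param cm a [confusion_matrix()] (or list with `tp`, `fn`, `fp`, `tn`).
#' @param conf_level confidence level (default 0.95).
#' @return an object of class `habsi_metrics`: a tibble with one row per
#'   metric (`metric`, `estimate`, `lower`, `upper`, `defined`,
#'   `display`), where `estimate` is a proportion in `[0,1]` (kappa in
#'   `[-1,1]`) and `display` is the half-up 2-decimal percentage (kappa:
#'   plain value) used in reports.
#' @examples
#' compute_metrics(confusion_matrix(tp = 160, fn = 3, fp = 7, tn = 17824))
#' @export
compute_metrics <- function(cm, conf_level = 0.95) {
  tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  n <- tp + fn + fp + tn
  if (n <= 0) abort_habsi("confusion matrix total must be positive")
  prop <- function(metric, x, d) {
    if (d == 0) {
      return(tibble::tibble(metric = metric, estimate = NA_real_,
                            lower = NA_real_, upper = NA_real_,
                            defined = FALSE, display = NA_real_))
    }
    ci <- clopper_pearson(x, d, conf_level)
    tibble::tibble(metric = metric, estimate = x / d,
                   lower = ci[["lower"]], upper = ci[["upper"]],
                   defined = TRUE, display = round_half_up(100 * x / d, 2))
  }
  p_o <- (tp + tn) / n
  p_e <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  if (p_e >= 1) {
    kap <- tibble::tibble(metric = "kappa", estimate = NA_real_, lower = NA_real_,
                          upper = NA_real_, defined = FALSE, display = NA_real_)
  } else {
    k <- (p_o - p_e) / (1 - p_e)
    se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    kap <- tibble::tibble(metric = "kappa", estimate = k,
                          lower = max(-1, k - z * se), upper = min(1, k + z * se),
                          defined = TRUE, display = round_half_up(k, 2))
  }
  out <- dplyr::bind_rows(
    prop("sensitivity", tp, tp + fn),
    prop("specificity", tn, tn + fp),
    prop("ppv", tp, tp + fp),
    prop("npv", tn, tn + fn),
    kap
  )
  structure(out, class = c("habsi_metrics", class(out)))
}

#' @export
print.habsi_metrics <- function(x, ...) {
  cat("<performance metrics>\n")
  for (i in seq_len(nrow(x))) {
    if (!x$defined[i]) {
      cat(sprintf("  %-12s undefined (zero denominator)\n", x$metric[i]))
    } else if (x$metric[i] == "kappa") {
      cat(sprintf("  %-12s %.2f (95%% CI %.2f-%.2f)\n", x$metric[i],
                  x$display[i], x$lower[i], x$upper[i]))
    } else {
      cat(sprintf("  %-12s %.2f%% (95%% CI %.2f-%.2f)\n", x$metric[i],
                  x$display[i], 100 * x$lower[i], 100 * x$upper[i]))
    }
  }
  invisible(x)
}

#' Pearson correlation between two count series
#'
#' Product-moment correlation with a two-sided test, for comparing event
#' counts per stratum (department, week) between two surveillance sources.
#'
#' @param series_a,series_b equal-length (>= 3) numeric count vectors.
#' @return list with `r`, `p_value`, `n`, `defined`; a zero-variance
#'   series gives `defined = FALSE` instead of an error.
#' @export
count_correlation <- function(series_a, series_b) {
  if (length(series_a) != length(series_b) || length(series_a) < 3) {
    abort_habsi("series must have equal length >= 3")
  }
  if (stats::sd(series_a) == 0 || stats::sd(series_b) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = length(series_a),
                defined = FALSE))
  }
  ct <- stats::cor.test(series_a, series_b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(series_a),
       defined = TRUE)
}

#' Confirmation-delay statistics by month
#'
#' The delay of an event is the whole-day difference between the
#' confirmation date and the log-in date of the first positive blood
#' specimen (the onset proxy). Events are grouped by the calendar month of
#' confirmation; the period mean is the unweighted average of the monthly
#' means (and the period SD the standard deviation of the monthly means),
#' matching how turnaround time is tracked on monthly surveillance
#' reports.
#'
#' @param events a tibble with `onset_ts` and `confirmation_ts` (events
#'   without a confirmation are dropped).
#' @return list with `monthly` (tibble `month`, `n`, `mean_delay_days`,
#'   `sd_delay_days`), `period_mean_days`, `period_sd_days`.
#' @export
delay_stats <- function(events) {
  ev <- events[!is.na(events$confirmation_ts), , drop = FALSE]
  if (!nrow(ev)) {
    return(list(monthly = tibble::tibble(month = character(0), n = integer(0),
                                         mean_delay_days = numeric(0),
                                         sd_delay_days = numeric(0)),
                period_mean_days = NA_real_, period_sd_days = NA_real_))
  }
  delay <- as.numeric(as.Date(fmt_ts(ev$confirmation_ts)) -
                        as.Date(fmt_ts(ev$onset_ts)))
  if (any(delay < 0)) {
    abort_habsi("negative confirmation delay: confirmation before onset",
                class = "habsi_data_error")
  }
  monthly <- tibble::tibble(
    month = format(as.Date(fmt_ts(ev$confirmation_ts)), "%Y-%m"),
    delay = delay
  ) |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_delay_days = mean(.data$delay),
                     sd_delay_days = stats::sd(.data$delay),
                     .groups = "drop") |>
    dplyr::arrange(.data$month)
  list(monthly = monthly,
       period_mean_days = mean(monthly$mean_delay_days),
       period_sd_days = stats::sd(monthly$mean_delay_days))
}

#' Incidence rates per 1000 patients and per 1000 patient-days
#'
#' `rate = 1000 * events / denominator`, pooled and (when a stratum column
#' is supplied) per stratum with the min-max range across strata. A
#' zero-denominator stratum is flagged undefined.
#'
#' @param n_events pooled event count, or a tibble of per-stratum counts
#'   with columns `stratum`, `n_events`.
#' @param denominators list with pooled `patients` and `patient_days`, or
#'   a tibble with `stratum`, `patients`, `patient_days`.
#' @return list with `pooled` (tibble `rate_per_1000_patients`,
#'   `rate_per_1000_patient_days`) and, for stratified input,
#'   `by_stratum` and `range` tibbles.
#' @export
incidence <- function(n_events, denominators) {
  rate <- function(ev, d) ifelse(d > 0, 1000 * ev / d, NA_real_)
  if (is.data.frame(n_events)) {
    den <- tibble::as_tibble(denominators)
    by <- dplyr::full_join(tibble::as_tibble(n_events), den, by = "stratum")
    by$n_events[is.na(by$n_events)] <- 0L
    by$rate_per_1000_patients <- rate(by$n_events, by$patients)
    by$rate_per_1000_patient_days <- rate(by$n_events, by$patient_days)
    by$defined <- by$patients > 0 & by$patient_days > 0
    pooled <- tibble::tibble(
      rate_per_1000_patients = rate(sum(by$n_events), sum(by$patients)),
      rate_per_1000_patient_days = rate(sum(by$n_events), sum(by$patient_days))
    )
    ok <- by$defined
    rng <- tibble::tibble(
      measure = c("rate_per_1000_patients", "rate_per_1000_patient_days"),
      min = c(min(by$rate_per_1000_patients[ok]), min(by$rate_per_1000_patient_days[ok])),
      max = c(max(by$rate_per_1000_patients[ok]), max(by$rate_per_1000_patient_days[ok]))
    )
    list(pooled = pooled, by_stratum = by, range = rng)
  } else {
    if (denominators$patients <= 0 || denominators$patient_days <= 0) {
      abort_habsi("denominators must be positive")
    }
    list(pooled = tibble::tibble(
      rate_per_1000_patients = rate(n_events, denominators$patients),
      rate_per_1000_patient_days = rate(n_events, denominators$patient_days)
    ))
  }
}
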