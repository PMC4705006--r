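test_that("patient-level confusion counts every patient exactly once", {
  expect_equal(
    unclass(patient_level_confusion("A", tibble::tibble(patient_id = "A", habsi = TRUE),
                                    c("A", "B")))[c("tp", "fn", "fp", "tn")],
    list(tp = 1L, fn = 0L, fp = 0L, tn = 1L))
  expect_equal(
    unclass(patient_level_confusion("A", tibble::tibble(patient_id = "B", habsi = TRUE),
                                    c("A", "B")))[c("tp", "fn", "fp", "tn")],
    list(tp = 0L, fn = 1L, fp = 1L, tn = 0L))
  expect_error(
    patient_level_confusion("A", tibble::tibble(patient_id = "Z", habsi = TRUE),
                            c("A", "B")),
    class = "habsi_data_error")

  # random assignments match a set-algebra oracle
  set.seed(8)
  for (rep in 1:5) {
    pop <- sprintf("P%03d", 1:200)
    truth <- sample(pop, 30)
    det <- sample(pop, 40)
    cm <- patient_level_confusion(det, tibble::tibble(patient_id = pop,
                                                      habsi = pop %in% truth), pop)
    expect_equal(cm$tp, length(intersect(det, truth)))
    expect_equal(cm$fp, length(setdiff(det, truth)))
    expect_equal(cm$fn, length(setdiff(truth, det)))
    expect_equal(cm$tn, length(setdiff(pop, union(det, truth))))
    expect_equal(cm$tp + cm$fn + cm$fp + cm$tn, 200)
  }
})

test_that("performance metrics match their closed-form definitions", {
  perfect <- compute_metrics(confusion_matrix(10, 0, 0, 90))
  expect_equal(perfect$estimate[perfect$metric != "kappa"], rep(1, 4))
  expect_equal(perfect$estimate[perfect$metric == "kappa"], 1)

  set.seed(12)
  for (rep in 1:10) {
    cm <- confusion_matrix(sample(1:50, 1), sample(0:10, 1),
                           sample(0:10, 1), sample(1:200, 1))
    m <- compute_metrics(cm)
    expect_equal(m$estimate[m$metric == "sensitivity"], cm$tp / (cm$tp + cm$fn))
    expect_equal(m$estimate[m$metric == "kappa"],
                 kappa_oracle(cm$tp, cm$fn, cm$fp, cm$tn))
    # kappa = 1 iff no discordant cells (both classes present)
    expect_equal(m$estimate[m$metric == "kappa"] == 1, cm$fp + cm$fn == 0)
    # CIs contain the estimate and live in [0, 1]
    ok <- m[m$defined & m$metric != "kappa", ]
    expect_true(all(ok$lower <= ok$estimate & ok$estimate <= ok$upper))
    expect_true(all(ok$lower >= 0 & ok$upper <= 1))
    # swapping the positive/negative labels swaps the paired metrics
    sw <- compute_metrics(confusion_matrix(cm$tn, cm$fp, cm$fn, cm$tp))
    expect_equal(sw$estimate[sw$metric == "sensitivity"],
                 m$estimate[m$metric == "specificity"])
    expect_equal(sw$estimate[sw$metric == "ppv"], m$estimate[m$metric == "npv"])
    expect_equal(sw$estimate[sw$metric == "kappa"], m$estimate[m$metric == "kappa"])
  }

  # zero denominators are flagged, not propagated
  none_pos <- compute_metrics(confusion_matrix(0, 0, 0, 50))
  expect_false(none_pos$defined[none_pos$metric == "sensitivity"])
  expect_true(is.na(none_pos$estimate[none_pos$metric == "sensitivity"]))
  # kappa under independence is near zero
  expect_lt(abs(compute_metrics(confusion_matrix(25, 25, 25, 25))$estimate[5]), 1e-12)
})

test_that("count correlation matches the product-moment formula", {
  x <- c(4, 9, 2, 11, 7)
  expect_equal(count_correlation(x, x)$r, 1)
  expect_equal(count_correlation(x, -x)$r, -1)
  set.seed(3)
  for (rep in 1:5) {
    a <- rpois(15, 8)
    b <- a + rpois(15, 3)
    cc <- count_correlation(a, b)
    expect_equal(cc$r, pearson_oracle(a, b), tolerance = 1e-12)
    expect_true(cc$defined)
  }
  flat <- count_correlation(rep(3, 5), c(1, 2, 3, 4, 5))
  expect_false(flat$defined)
  expect_error(count_correlation(1:2, 1:2), "length")
})

test_that("confirmation delay is grouped by confirmation month, averaged unweighted", {
  ev <- tibble::tibble(
    onset_ts = habsi:::parse_ts(c("2012-10-15T08:00", "2012-10-20T08:00",
                                  "2012-11-10T08:00")),
    confirmation_ts = habsi:::parse_ts(c("2012-10-20T10:00", "2012-10-23T09:00",
                                         "2012-11-16T08:00")))
  ds <- delay_stats(ev)
  # whole-day differences: 5 and 3 in October (mean 4), 6 in November
  expect_equal(ds$monthly$mean_delay_days, c(4, 6))
  # period mean is the unweighted mean of monthly means
  expect_equal(ds$period_mean_days, 5)
  bad <- ev
  bad$confirmation_ts[1] <- habsi:::parse_ts("2012-10-01T00:00")
  expect_error(delay_stats(bad), class = "habsi_data_error")

  # random event sets match a brute-force per-month grouping oracle
  set.seed(21)
  for (rep in 1:3) {
    n <- 40
    onset <- habsi:::parse_ts("2012-01-01T00:00") + sample(0:200, n, TRUE) * 86400
    conf <- onset + sample(0:60, n, TRUE) * 86400 + sample(0:23, n, TRUE) * 3600
    evr <- tibble::tibble(onset_ts = onset, confirmation_ts = conf)
    ds <- delay_stats(evr)
    dd <- as.numeric(as.Date(format(conf, "%Y-%m-%d")) -
                       as.Date(format(onset, "%Y-%m-%d")))
    by_m <- split(dd, format(conf, "%Y-%m"))
    expect_equal(ds$monthly$mean_delay_days,
                 unname(vapply(by_m, mean, numeric(1))[sort(names(by_m))]))
    expect_equal(ds$period_mean_days, mean(vapply(by_m, mean, numeric(1))))
  }
})

test_that("incidence rates are plain scaled ratios with stratum ranges", {
  pooled <- incidence(2, list(patients = 500, patient_days = 1000))
  expect_equal(pooled$pooled$rate_per_1000_patient_days, 2.0)
  expect_equal(incidence(0, list(patients = 10, patient_days = 10))$
                 pooled$rate_per_1000_patients, 0)
  expect_error(incidence(1, list(patients = 0, patient_days = 10)), "positive")

  set.seed(5)
  ev <- tibble::tibble(stratum = sprintf("D%02d", 1:8),
                       n_events = rpois(8, 4))
  den <- tibble::tibble(stratum = sprintf("D%02d", 1:8),
                        patients = sample(100:500, 8),
                        patient_days = sample(1000:4000, 8))
  out <- incidence(ev, den)
  expect_equal(out$by_stratum$rate_per_1000_patients,
               1000 * ev$n_events / den$patients)
  expect_equal(out$pooled$rate_per_1000_patient_days,
               1000 * sum(ev$n_events) / sum(den$patient_days))
  expect_equal(out$range$min[1], min(1000 * ev$n_events / den$patients))
  # zero-denominator stratum flagged undefined, not an error
  den$patients[1] <- 0
  out2 <- incidence(ev, den)
  expect_false(out2$by_stratum$defined[1])
})
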