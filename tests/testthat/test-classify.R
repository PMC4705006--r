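test_that("polymicrobial and persistent criteria deduplicate as specified", {
  cfg <- habsi_config()
  # two organisms in the same draw window: one polymicrobial event
  ev <- merge_events(make_cands(
    list(onset = "2012-10-03T08:00", orgs = "Escherichia coli"),
    list(onset = "2012-10-03T10:00", orgs = "Klebsiella pneumoniae")), cfg)
  expect_equal(nrow(ev), 1)
  expect_setequal(ev$organisms[[1]], c("Escherichia coli", "Klebsiella pneumoniae"))
  # same organism at day 3 and day 10: persistent, one event
  ev2 <- merge_events(make_cands(
    list(onset = "2012-10-03T08:00", orgs = "Escherichia coli"),
    list(onset = "2012-10-10T08:00", orgs = "Escherichia coli")), cfg)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$n_candidates, 2L)
  # same organism at day 3 and day 25: a genuinely new event
  ev3 <- merge_events(make_cands(
    list(onset = "2012-10-03T08:00", orgs = "Escherichia coli"),
    list(onset = "2012-10-25T08:00", orgs = "Escherichia coli")), cfg)
  expect_equal(nrow(ev3), 2)
  # different organism beyond the polymicrobial window: new event too
  ev4 <- merge_events(make_cands(
    list(onset = "2012-10-03T08:00", orgs = "Escherichia coli"),
    list(onset = "2012-10-10T08:00", orgs = "Candida albicans")), cfg)
  expect_equal(nrow(ev4), 2)
})

test_that("the persistent window is anchored at event onset, not extended", {
  cfg <- habsi_config()
  ev <- merge_events(make_cands(
    list(onset = "2012-10-01T00:00", orgs = "Escherichia coli"),
    list(onset = "2012-10-12T00:00", orgs = "Escherichia coli"),
    list(onset = "2012-10-22T00:00", orgs = "Escherichia coli")), cfg)
  # day 12 absorbed (<= 14 d from day 1); day 22 is past the window and
  # does not chain off the absorbed day-12 candidate
  expect_equal(nrow(ev), 2)
  expect_equal(ev$n_candidates, c(2L, 1L))
})

test_that("deduplication conserves candidates and is idempotent", {
  cfg <- habsi_config()
  set.seed(31)
  for (rep in 1:5) {
    n <- 12
    orgs_pool <- c("Escherichia coli", "Klebsiella pneumoniae", "Candida albicans")
    rows <- lapply(seq_len(n), function(i) {
      list(onset = habsi:::fmt_ts(habsi:::parse_ts("2012-10-01T00:00") +
                                    sample(0:40, 1) * 86400 + sample(0:23, 1) * 3600),
           orgs = sample(orgs_pool, sample(1:2, 1)))
    })
    cand <- do.call(make_cands, rows)
    ev <- merge_events(cand, cfg)
    # conservation: absorbed + events == candidates
    expect_equal(sum(ev$n_candidates), nrow(cand))
    expect_equal(anyDuplicated(unlist(ev$source_specimens)), 0)
    # idempotence on its own output
    re <- ev
    re$candidate_id <- re$event_id
    re$pathway <- "culture"
    ev2 <- merge_events(re, cfg)
    expect_equal(nrow(ev2), nrow(ev))
    expect_equal(lapply(ev2$organisms, sort), lapply(ev$organisms, sort))
  }
  # limit case: zero windows leave one event per candidate, even with ties
  tied <- make_cands(
    list(onset = "2012-10-03T08:00", orgs = "Escherichia coli"),
    list(onset = "2012-10-03T08:00", orgs = "Escherichia coli"))
  expect_equal(nrow(merge_events(tied, habsi_config(polymicrobial_hours = 0,
                                                    persistent_days = 0))), 2)
})

test_that("classification precedence is CSEP > SEC > CRBSI > CLABSI > OTHER", {
  cfg <- habsi_config()
  ev <- merge_events(make_cands(
    list(onset = "2012-10-05T00:00", orgs = "Klebsiella pneumoniae")), cfg)
  no_cult <- habsi:::empty_cultures()
  no_dev <- habsi:::empty_devices()
  line <- tibble::tibble(patient_id = "P1", device_type = "central_line",
                         start_ts = habsi:::parse_ts("2012-10-01T00:00"),
                         end_ts = habsi:::parse_ts("2012-10-08T00:00"))
  urine <- culture_fixture("U1", "P1", "2012-10-03T00:00", type = "urine",
                           orgs = "Klebsiella pneumoniae")
  tip <- culture_fixture("T1", "P1", "2012-10-06T00:00", type = "catheter_tip",
                         orgs = "Klebsiella pneumoniae")
  # matching organism from another site two days before onset: secondary
  expect_equal(classify(ev, urine, no_dev, cfg), "SEC")
  # secondary wins even when catheter evidence is also present
  expect_equal(classify(ev, dplyr::bind_rows(urine, tip), line, cfg), "SEC")
  # line + concordant tip: catheter-related
  expect_equal(classify(ev, tip, line, cfg), "PRIM_CRBSI")
  # line without tip concordance: line-associated
  expect_equal(classify(ev, no_cult, line, cfg), "PRIM_CLABSI")
  # neither device nor other site: other primary
  expect_equal(classify(ev, no_cult, no_dev, cfg), "PRIM_OTHER")
  # a tip culture alone never makes the event secondary
  expect_equal(classify(ev, tip, no_dev, cfg), "PRIM_OTHER")
  # commensal growth at another site does not count as a secondary source
  u2 <- culture_fixture("U2", "P1", "2012-10-03T00:00", type = "urine",
                        orgs = "Staphylococcus epidermidis")
  ev_cons <- merge_events(make_cands(
    list(onset = "2012-10-05T00:00", orgs = "Staphylococcus epidermidis")), cfg)
  expect_equal(classify(ev_cons, u2, no_dev, cfg), "PRIM_OTHER")
  # sepsis pathway is always CSEP
  ev_csep <- merge_events(make_cands(
    list(onset = "2012-10-05T00:00", pathway = "sepsis")), cfg)
  expect_equal(classify(ev_csep, urine, line, cfg), "CSEP")
})

test_that("the pipeline reproduces the hand-derived fixture event list", {
  fx <- hand_fixture()
  res <- run_pipeline(fx$bundle)
  ev <- res$events
  got <- ev[order(ev$patient_id),
            c("patient_id", "classification")]
  got$n_organisms <- lengths(ev$organisms[order(ev$patient_id)])
  expect_equal(as.data.frame(got),
               as.data.frame(fx$expected[order(fx$expected$patient_id), ]))
  expect_false(any(fx$negatives %in% ev$patient_id))
  # funnel bookkeeping
  f <- res$funnel
  expect_equal(f$n_events, nrow(ev))
  expect_equal(f$n_candidates - f$n_candidates_absorbed, f$n_events)
  expect_equal(sum(unlist(f$events_by_classification)), f$n_events)
  # exactly one label per event, from the closed label set
  expect_true(all(ev$classification %in%
                    c("PRIM_CRBSI", "PRIM_CLABSI", "PRIM_OTHER", "SEC", "CSEP")))
  # CSEP if and only if no organisms
  expect_equal(ev$classification == "CSEP", lengths(ev$organisms) == 0)
})

test_that("pipeline output is invariant to input row order", {
  fx <- hand_fixture()
  res1 <- run_pipeline(fx$bundle)
  set.seed(4)
  shuffled <- fx$bundle
  for (s in names(shuffled)) {
    shuffled[[s]] <- shuffled[[s]][sample(nrow(shuffled[[s]])), ]
  }
  res2 <- run_pipeline(shuffled)
  expect_equal(res1$events, res2$events)
  expect_equal(res1$funnel, res2$funnel)
})

test_that("an empty bundle yields zero events and an all-zero funnel", {
  b <- habsi_bundle(validate_stays(stay_row("P1", "S1", "2012-10-01T00:00",
                                            "2012-10-02T00:00"))[0, ])
  res <- run_pipeline(b)
  expect_equal(nrow(res$events), 0)
  expect_equal(res$funnel$n_candidates, 0)
  expect_equal(res$funnel$n_events, 0)
})
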