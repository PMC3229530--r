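test_that("exposure states follow the 3- and 12-month cut points", {
  d0 <- as.Date("2004-01-01")
  expect_identical(classify_exposure(d0, d0 + c(0, 45, 90, 91, 200, 364,
                                                365, 400)),
                   c("current", "current", "current", "recent", "recent",
                     "recent", "past", "past"))
  expect_identical(classify_exposure(as.Date(character(0)),
                                     d0 + c(0, 500)),
                   c("never", "never"))
  ## a repeat prescription extends the current window: rx at day 0 and 60
  ## keeps the patient current throughout [0, 151)
  rx <- d0 + c(0, 60)
  states <- classify_exposure(rx, d0 + 0:150)
  expect_true(all(states == "current"))
  expect_identical(classify_exposure(rx, d0 + c(100, 151)),
                   c("current", "recent"))
  ## queries before the first prescription are never, not an error
  expect_identical(classify_exposure(d0, d0 - 10), "never")
})

test_that("a single prescription tiles follow-up into current/recent/past", {
  pat <- make_patients(1L, data_start = as.Date("2002-06-01"),
                       data_end = as.Date("2006-12-31"),
                       birth_year = 1950L)
  idx <- as.Date("2004-01-01")
  rx <- make_rx(1L, idx, "metformin")
  coh <- data.table(patient_id = 1L, cohort = "inception:metformin",
                    index_date = idx, censor_date = idx + 400L)
  seg <- split_person_time(coh, pat, rx, classes = "metformin")
  ## conservation
  expect_identical(sum(seg$days), 400L)
  expect_identical(seg$start[1], idx)
  expect_identical(seg$end[nrow(seg)], idx + 400L)
  ## runs of identical state reproduce the 91/365 day windows
  runs <- seg[, .(from = min(start), to = max(end)),
              by = state_metformin]
  expect_identical(runs$state_metformin, c("current", "recent", "past"))
  expect_identical(as.numeric(runs$to - idx), c(91, 365, 400))
})

test_that("reference-class censoring ends person-time at its first use", {
  pat <- make_patients(1L, data_start = as.Date("2000-01-01"),
                       data_end = as.Date("2009-12-31"))
  idx <- as.Date("2003-01-01")
  rx <- rbind(make_rx(1L, idx, "rosiglitazone"),
              make_rx(1L, idx + 300L, "pioglitazone"))
  coh <- data.table(patient_id = 1L, cohort = "inception:rosiglitazone",
                    index_date = idx, censor_date = as.Date("2009-12-31"))
  seg <- split_person_time(coh, pat, rx, reference_class = "pioglitazone",
                          classes = c("rosiglitazone", "pioglitazone"))
  expect_identical(max(seg$end), idx + 300L)
  expect_identical(sum(seg$days), 300L)
})

test_that("segment labels agree with the day-resolution oracle", {
  cfg <- small_scenario(seed = 17L, n = 200L)
  tabs <- simulate_ehr(cfg)
  coh <- build_exposed_cohort(tabs$patients, tabs$prescriptions)
  seg <- split_person_time(coh, tabs$patients, tabs$prescriptions)
  rxe <- tzdsafety:::expand_rx(tabs$prescriptions)
  ## expand every segment to day resolution and compare per class
  mism <- 0L
  for (pid in unique(seg$patient_id)) {
    s <- seg[patient_id == pid][order(start)]
    all_days <- seq(as.numeric(min(s$start)), as.numeric(max(s$end)) - 1)
    for (cl in drug_classes()) {
      lab <- rep(s[[paste0("state_", cl)]], s$days)
      rx_days <- as.numeric(rxe[patient_id == pid & drug_class == cl,
                                date])
      oracle <- oracle_classify_days(rx_days, all_days)
      mism <- mism + sum(lab != oracle)
    }
  }
  expect_identical(mism, 0L)
})

test_that("person-time tiling is conserved on random cohorts", {
  cfg <- small_scenario(seed = 18L, n = 500L)
  tabs <- simulate_ehr(cfg)
  coh <- build_exposed_cohort(tabs$patients, tabs$prescriptions)
  seg <- split_person_time(coh, tabs$patients, tabs$prescriptions,
                           tabs$covariates)
  tot <- seg[, .(tiled = sum(days), lo = min(start), hi = max(end)),
             by = entry]
  coh[, entry := .I]
  chk <- merge(tot, coh, by = "entry")
  expect_true(all(chk$tiled ==
                    as.numeric(chk$censor_date - chk$index_date)))
  expect_true(all(chk$lo == chk$index_date))
  expect_true(all(chk$hi == chk$censor_date))
  ## segments are disjoint and ordered
  setorder(seg, entry, start)
  gaps <- seg[, .(ok = all(head(end, -1L) == tail(start, -1L))),
              by = entry]
  expect_true(all(gaps$ok))
})

test_that("no current person-time precedes the first prescription", {
  cfg <- small_scenario(seed = 19L, n = 400L)
  tabs <- simulate_ehr(cfg)
  coh <- build_exposed_cohort(tabs$patients, tabs$prescriptions)
  seg <- split_person_time(coh, tabs$patients, tabs$prescriptions)
  rxe <- tzdsafety:::expand_rx(tabs$prescriptions)
  for (cl in drug_classes()) {
    first <- rxe[drug_class == cl, .(first = min(date)), by = patient_id]
    cur <- merge(seg[seg[[paste0("state_", cl)]] == "current"],
                 first, by = "patient_id")
    expect_true(all(cur$start >= cur$first), label = cl)
  }
  ## state sequence never reverses: per entry and class, the state rank
  ## (never < current < recent < past) after the final prescription is
  ## non-decreasing
  rank_of <- c(current = 1L, recent = 2L, past = 3L)
  for (cl in drug_classes()) {
    lastrx <- rxe[drug_class == cl, .(last = max(date)), by = patient_id]
    s <- merge(seg, lastrx, by = "patient_id")
    s <- s[start >= last & s[[paste0("state_", cl)]] != "never"]
    if (!nrow(s)) next
    setorder(s, entry, start)
    ok <- s[, .(mono = !is.unsorted(rank_of[get(paste0("state_", cl))])),
            by = entry]
    expect_true(all(ok$mono), label = cl)
  }
})

test_that("events are attributed to the containing segment and truncate it", {
  pat <- make_patients(1L, data_start = as.Date("2002-01-01"),
                       data_end = as.Date("2006-12-31"),
                       birth_year = 1950L)
  idx <- as.Date("2004-01-01")
  rx <- make_rx(1L, idx, "metformin")
  coh <- data.table(patient_id = 1L, cohort = "x", index_date = idx,
                    censor_date = idx + 400L)
  seg <- split_person_time(coh, pat, rx, classes = "metformin")
  ## death on day 100 sits in the recent segment [91, 365): the segment is
  ## truncated to end the day after death and later segments are dropped
  a <- attribute_events(seg, data.table(patient_id = 1L,
                                        date = idx + 100L),
                        outcome = "death")
  expect_identical(sum(a$events), 1L)
  hit <- a[events == 1L]
  expect_identical(hit$state_metformin, "recent")
  expect_identical(hit$end, idx + 101L)
  expect_identical(max(a$end), idx + 101L)
  ## interval-membership oracle: the event day lies in exactly one segment
  expect_identical(sum(seg$start <= idx + 100L & seg$end > idx + 100L), 1L)

  ## zero events: counts zero, person-time unchanged
  a0 <- attribute_events(seg, data.table(patient_id = integer(0),
                                         date = as.Date(character(0))),
                         outcome = "death")
  expect_identical(sum(a0$events), 0L)
  expect_identical(sum(a0$days), sum(seg$days))

  ## an event outside follow-up is ignored with a warning
  expect_warning(
    attribute_events(seg, data.table(patient_id = 1L,
                                     date = idx + 500L),
                     outcome = "death"),
    "outside follow-up")
})

test_that("pre-index outcomes exclude the patient from that outcome only", {
  pat <- make_patients(2L, data_start = as.Date("2000-01-01"),
                       data_end = as.Date("2008-12-31"))
  idx <- as.Date("2003-01-01")
  rx <- make_rx(c(1L, 2L), idx, "metformin")
  coh <- data.table(patient_id = c(1L, 2L), cohort = "x",
                    index_date = idx, censor_date = idx + 200L)
  seg <- split_person_time(coh, pat, rx, classes = "metformin")
  ## patient 1 had an ACS before index
  acs <- data.table(patient_id = 1L, date = as.Date("2002-05-01"),
                    outcome = "acs")
  a_acs <- attribute_events(seg, acs, outcome = "acs",
                            incident_only = TRUE)
  expect_false(1L %in% a_acs$patient_id)
  expect_true(2L %in% a_acs$patient_id)
  ## the same patient still contributes to the death analysis
  a_death <- attribute_events(seg, data.table(patient_id = integer(0),
                                              date = as.Date(character(0))),
                              outcome = "death")
  expect_true(1L %in% a_death$patient_id)
})

test_that("duplicate and unordered prescriptions are idempotent", {
  pat <- make_patients(1L, data_start = as.Date("2002-01-01"),
                       data_end = as.Date("2006-12-31"))
  idx <- as.Date("2004-01-01")
  coh <- data.table(patient_id = 1L, cohort = "x", index_date = idx,
                    censor_date = idx + 300L)
  rx1 <- make_rx(1L, idx, "metformin")
  rx2 <- make_rx(rep(1L, 3L), c(idx, idx, idx), "metformin")
  s1 <- split_person_time(coh, pat, rx1, classes = "metformin")
  s2 <- split_person_time(coh, pat, rx2[c(2, 1, 3)],
                          classes = "metformin")
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})
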