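test_that("index date requires a prescription one year into data collection", {
  pat <- make_patients(1L, data_start = as.Date("2000-01-01"),
                       data_end = as.Date("2006-12-31"))
  ## only prescription 5 months in: not eligible
  rx_early <- make_rx(1L, "2000-06-01", "metformin")
  expect_identical(nrow(build_exposed_cohort(pat, rx_early)), 0L)
  ## no prescriptions at all: not eligible
  expect_identical(nrow(build_exposed_cohort(pat, rx_early[0])), 0L)
  ## second prescription after the run-in qualifies; the earlier one is
  ## ignored for the index but stays in history
  rx_two <- make_rx(c(1L, 1L), c("2000-06-01", "2001-03-01"), "metformin")
  coh <- build_exposed_cohort(pat, rx_two)
  expect_identical(nrow(coh), 1L)
  expect_identical(coh$index_date, as.Date("2001-03-01"))
  ## day-count oracle for the run-in rule
  expect_gte(as.numeric(coh$index_date - pat$data_start), 365)
})

test_that("the one-year boundary is inclusive", {
  pat <- make_patients(1L, data_start = as.Date("2000-01-01"))
  rx <- make_rx(1L, pat$data_start + 365L, "sulphonylurea")
  coh <- build_exposed_cohort(pat, rx)
  expect_identical(nrow(coh), 1L)
  expect_identical(coh$index_date, pat$data_start + 365L)
})

test_that("type-1 patients and unknown patients are handled", {
  pat <- make_patients(2L)
  pat[1L, type1 := TRUE]
  rx <- make_rx(c(1L, 2L), c("2002-01-01", "2002-01-01"), "insulin")
  coh <- build_exposed_cohort(pat, rx)
  expect_identical(coh$patient_id, 2L)
  expect_error(build_exposed_cohort(pat, make_rx(9L, "2002-01-01",
                                                 "insulin")),
               "unknown patients")
})

test_that("inception cohorts use first-ever prescriptions per class", {
  pat <- make_patients(1L, data_start = as.Date("1999-01-01"),
                       data_end = as.Date("2006-12-31"))
  ## sulphonylurea started during the first year: never a new user there;
  ## metformin started much later: a new user of metformin
  rx <- rbind(make_rx(1L, "1999-07-01", "sulphonylurea"),
              make_rx(1L, "2001-05-01", "metformin"),
              make_rx(1L, "2001-09-01", "sulphonylurea"))
  metf <- build_inception_cohort(pat, rx, "metformin")
  expect_identical(nrow(metf), 1L)
  expect_identical(metf$index_date, as.Date("2001-05-01"))
  expect_identical(metf$cohort, "inception:metformin")
  sulf <- build_inception_cohort(pat, rx, "sulphonylurea")
  expect_identical(nrow(sulf), 0L)
  expect_error(build_inception_cohort(pat, rx, "biguanide"),
               "unknown drug class")
})

test_that("multi-constituent prescriptions enter both class histories", {
  pat <- make_patients(1L, data_start = as.Date("2000-01-01"))
  rx <- make_rx(1L, "2002-03-01", "rosiglitazone",
                multi_constituent = "metformin")
  rosi <- build_inception_cohort(pat, rx, "rosiglitazone")
  metf <- build_inception_cohort(pat, rx, "metformin")
  expect_identical(rosi$index_date, as.Date("2002-03-01"))
  expect_identical(metf$index_date, as.Date("2002-03-01"))
})

test_that("matching picks the nearest age within tolerance, exactly", {
  ## exposed aged 64 at index; candidates aged 63 and 66 in the same
  ## practice and sex; enumerating the pool by hand: |63-64| = 1 beats
  ## |66-64| = 2
  pat <- make_patients(3L, birth_year = 1940L,
                       data_start = as.Date("2000-01-01"),
                       data_end = as.Date("2009-12-31"))
  pat[2L, birth_year := 1941L]  # age 63 at 2004-07-01 index
  pat[3L, birth_year := 1938L]  # age 66
  rx <- make_rx(1L, "2004-07-01", "metformin")
  exposed <- build_exposed_cohort(pat, rx)
  ctl <- match_controls(exposed, pat, rx, match_criteria(5), seed = 1L)
  expect_identical(nrow(ctl), 1L)
  expect_identical(ctl$patient_id, 2L)
  expect_identical(ctl$matched_to, 1L)
  expect_identical(ctl$index_date, exposed$index_date)
  ## empty candidate pool: exposed flagged unmatched, not dropped
  lone <- make_patients(1L)
  rx1 <- make_rx(1L, "2002-01-01", "metformin")
  exp1 <- build_exposed_cohort(lone, rx1)
  ctl1 <- match_controls(exp1, lone, rx1, match_criteria(5), seed = 1L)
  expect_identical(nrow(ctl1), 0L)
  expect_identical(attr(ctl1, "unmatched"), 1L)
})

test_that("a control later starting an antidiabetic is censored there", {
  pat <- make_patients(2L, data_start = as.Date("2000-01-01"),
                       data_end = as.Date("2009-12-31"))
  rx <- rbind(make_rx(1L, "2002-01-01", "metformin"),
              make_rx(2L, "2005-06-15", "metformin"))
  exposed <- build_exposed_cohort(pat, rx)[patient_id == 1L]
  ctl <- match_controls(exposed, pat, rx, match_criteria(5), seed = 1L)
  expect_identical(ctl$patient_id, 2L)
  expect_identical(ctl$censor_date, as.Date("2005-06-15"))
})

test_that("matching is deterministic and respects all criteria", {
  cfg <- small_scenario(seed = 14L, n = 800L)
  tabs <- simulate_ehr(cfg)
  exposed <- build_exposed_cohort(tabs$patients, tabs$prescriptions)
  c1 <- match_controls(exposed, tabs$patients, tabs$prescriptions,
                       seed = 99L)
  c2 <- match_controls(exposed, tabs$patients, tabs$prescriptions,
                       seed = 99L)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_identical(anyDuplicated(c1$patient_id), 0L)
  expect_identical(anyDuplicated(c1$matched_to), 0L)

  pat <- tabs$patients
  chk <- merge(c1, pat[, .(patient_id, practice_id, sex, birth_year)],
               by = "patient_id")
  chk <- merge(chk, pat[, .(matched_to = patient_id,
                            e_practice = practice_id, e_sex = sex,
                            e_birth = birth_year)], by = "matched_to")
  expect_true(all(chk$practice_id == chk$e_practice))
  expect_true(all(chk$sex == chk$e_sex))
  age_c <- age_diff <- abs(
    floor(as.numeric(chk$index_date - as.Date(paste0(chk$birth_year, "-07-01"))) / 365.25) -
    floor(as.numeric(chk$index_date - as.Date(paste0(chk$e_birth, "-07-01"))) / 365.25))
  expect_true(all(age_diff <= 5))
  ## controls have no antidiabetic prescription before the index date
  first_rx <- tabs$prescriptions[, .(first = min(date)), by = patient_id]
  chk2 <- merge(c1, first_rx, by = "patient_id", all.x = TRUE)
  expect_true(all(is.na(chk2$first) | chk2$first > chk2$index_date))
})

test_that("no exposed index date precedes the run-in on generated data", {
  cfg <- small_scenario(seed = 16L, n = 800L)
  tabs <- simulate_ehr(cfg)
  pat <- tabs$patients
  for (coh in list(build_exposed_cohort(pat, tabs$prescriptions),
                   build_inception_cohort(pat, tabs$prescriptions,
                                          "metformin"),
                   build_inception_cohort(pat, tabs$prescriptions,
                                          "rosiglitazone"))) {
    m <- merge(coh, pat[, .(patient_id, data_start)], by = "patient_id")
    expect_true(all(as.numeric(m$index_date - m$data_start) >= 365))
    expect_true(all(m$index_date < m$censor_date))
  }
})
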