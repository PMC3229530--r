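test_that("incidence rates are events per 100 person-years", {
  expect_identical(incidence_rate(0, 123.4), 0)
  expect_identical(incidence_rate(5, 250), 2)
  expect_error(incidence_rate(1, 0), "positive")
  expect_error(incidence_rate(1, -5), "positive")
})

## minimal person-time table accepted by fit_rate_model
cells_dt <- function(exposure, events, py, ...) {
  data.table(exposure = exposure, events = events, py = py, ...)
}

test_that("the crude two-group model reproduces the analytic rate ratio", {
  d <- cells_dt(c("a", "b"), c(20L, 10L), c(1000, 1000))
  f <- fit_rate_model(d, adjustment = "none", reference = "b")
  t <- f$terms[level == "a"]
  ## saturated model: RR equals the ratio of rates exactly
  expect_equal(t$RR, 2, tolerance = 1e-10)
  ## Wald CI on the log scale with z = 1.96
  se <- sqrt(1 / 20 + 1 / 10)
  expect_equal(t$lower, exp(log(2) - 1.96 * se), tolerance = 1e-8)
  expect_equal(t$upper, exp(log(2) + 1.96 * se), tolerance = 1e-8)
  expect_equal(f$rates[level == "a", rate], 2)
})

test_that("adjusted fits match a derivative-free likelihood oracle", {
  ## one binary confounder, four hand-chosen cells
  d <- cells_dt(exposure = c("e", "e", "u", "u"),
                events = c(30L, 9L, 14L, 4L),
                py = c(500, 300, 700, 450),
                age_band = c("40-49", "85+", "40-49", "85+"))
  f <- fit_rate_model(d, adjustment = "minimal", reference = "u")
  X <- cbind(1, d$exposure == "e", d$age_band == "85+")
  beta <- oracle_poisson_fit(X, d$events, d$py,
                             start = c(log(sum(d$events) / sum(d$py)), 0, 0))
  expect_equal(unname(f$terms[level == "e", logRR]), beta[2],
               tolerance = 1e-6)
  expect_equal(unname(coef(f$model)[["age_band85+"]]), beta[3],
               tolerance = 1e-6)
})

test_that("fitting segments or aggregated cells gives identical estimates", {
  ## Poisson sufficiency: split each cell's person-time into random
  ## sub-rows; estimates must not move
  set.seed(42)
  d <- cells_dt(exposure = rep(c("e", "u"), each = 2L),
                events = c(12L, 7L, 9L, 11L),
                py = c(400, 350, 500, 600),
                age_band = rep(c("40-49", "65-74"), 2L))
  rows <- list()
  for (i in seq_len(nrow(d))) {
    w <- as.vector(rmultinom(1, 1000, runif(4))) / 1000
    ev <- as.vector(rmultinom(1, d$events[i], w))
    rows[[i]] <- data.table(exposure = d$exposure[i],
                            age_band = d$age_band[i],
                            events = ev, py = d$py[i] * w)
  }
  fine <- rbindlist(rows)[py > 0]
  f_cells <- fit_rate_model(d, adjustment = "minimal", reference = "u")
  f_fine <- fit_rate_model(fine, adjustment = "minimal", reference = "u")
  expect_equal(coef(f_cells$model), coef(f_fine$model), tolerance = 1e-8)
})

test_that("separation is flagged with infinite confidence limits", {
  d <- cells_dt(c("a", "b"), c(15L, 0L), c(100, 100))
  f <- fit_rate_model(d, adjustment = "none", reference = "a")
  t <- f$terms[level == "b"]
  expect_true(t$separated)
  expect_identical(t$lower, 0)
  expect_identical(t$upper, Inf)
})

test_that("stratified fits split, mark empty strata, and match pooled fits
           when the stratum is constant", {
  d <- cells_dt(exposure = rep(c("e", "u"), 4L),
                events = c(8L, 5L, 12L, 9L, 7L, 6L, 10L, 8L),
                py = rep(c(300, 400), 4L),
                age_band = rep(c("50-64", "50-64", "65-74", "65-74"), 2L),
                calendar_year = rep(c(2005L, 2008L), each = 4L))
  d[, state_insulin := "never"]
  by_cal <- run_stratified(d, "calendar2007", adjustment = "none",
                           reference = "u")
  expect_named(by_cal, c("<2007", ">=2007"))
  expect_s3_class(by_cal[["<2007"]], "rate_model_fit")
  ## insulin stratum is constant: the single stratum equals the pooled fit
  by_ins <- run_stratified(d, "insulin", adjustment = "none",
                           reference = "u")
  expect_length(by_ins, 1L)
  pooled <- fit_rate_model(d, adjustment = "none", reference = "u")
  expect_equal(coef(by_ins[[1]]$model), coef(pooled$model),
               tolerance = 1e-12)
  ## a stratum with no events is reported not-estimable, not fatal
  d2 <- copy(d)[calendar_year >= 2007, events := 0L]
  by_cal2 <- run_stratified(d2, "calendar2007", adjustment = "none",
                            reference = "u")
  expect_s3_class(by_cal2[[">=2007"]], "not_estimable")
})

test_that("a calendar-straddling segment is split before stratification", {
  pat <- make_patients(1L, data_start = as.Date("2004-01-01"),
                       data_end = as.Date("2009-12-31"),
                       birth_year = 1950L)
  idx <- as.Date("2006-10-01")
  rx <- make_rx(1L, idx, "metformin")
  coh <- data.table(patient_id = 1L, cohort = "x", index_date = idx,
                    censor_date = as.Date("2007-03-01"))
  seg <- split_person_time(coh, pat, rx, classes = "metformin")
  ## the year boundary 2007-01-01 must be a segment boundary
  expect_true(as.Date("2007-01-01") %in% seg$start)
  expect_identical(sort(unique(seg$calendar_year)), c(2006L, 2007L))
  ## and the stratum assignment is exact on either side
  v <- tzdsafety:::stratum_values(seg, "calendar2007")
  expect_identical(v, fifelse(seg$start < as.Date("2007-01-01"),
                              "<2007", ">=2007"))
})

test_that("estimate error shrinks with sample size under the known truth", {
  run_once <- function(n, seed) {
    cfg <- scenario_config(
      n_patients = n, n_practices = 50L, channeling_strength = 0,
      true_log_rr = c("rosiglitazone:death" = log(1.2)), seed = seed)
    tabs <- simulate_ehr(cfg)
    seg <- tzdsafety:::contrast_person_time(tabs, "rosiglitazone",
                                            "pioglitazone")
    a <- attribute_events(seg,
                          tabs$patients[!is.na(death_date),
                                        .(patient_id, date = death_date)],
                          outcome = "death")
    cu <- current_use_contrast(a, c("rosiglitazone", "pioglitazone"))
    f <- fit_rate_model(cu, adjustment = "minimal",
                        exclude_classes = c("rosiglitazone",
                                            "pioglitazone"))
    f$terms[level == "rosiglitazone", .(logRR, se)]
  }
  small <- run_once(4000L, seed = 51L)
  large <- run_once(16000L, seed = 52L)
  truth <- log(1.2)
  ## standard errors shrink and the larger run stays near the truth
  expect_lt(large$se, small$se)
  expect_lt(abs(large$logRR - truth), 3 * large$se)
  ## |bias| decreases within Monte-Carlo error
  expect_lt(abs(large$logRR - truth),
            abs(small$logRR - truth) + 2 * (small$se + large$se))
})
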