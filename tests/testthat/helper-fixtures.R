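## Hand-built fixture tables and independent oracles used across tests.

library(data.table)

## minimal patient table with all generator columns
make_patients <- function(n = 1L,
                          data_start = as.Date("2000-01-01"),
                          data_end = as.Date("2006-12-31"),
                          birth_year = 1940L,
                          sex = "M",
                          practice_id = 1L,
                          linked = TRUE,
                          death_date = as.Date(NA)) {
  data.table(
    patient_id = seq_len(n),
    practice_id = rep_len(practice_id, n),
    linked = rep_len(linked, n),
    ses_quintile = 3L,
    sex = rep_len(sex, n),
    birth_year = rep_len(birth_year, n),
    data_start = rep_len(data_start, n),
    data_end = rep_len(data_end, n),
    type1 = FALSE,
    latent_severity = 0,
    death_date = rep_len(death_date, n),
    death_source = ""
  )
}

make_rx <- function(patient_id, dates, drug_class,
                    multi_constituent = NA_character_) {
  data.table(patient_id = patient_id, date = as.Date(dates),
             drug_class = drug_class,
             multi_constituent = multi_constituent)
}

## small generator scenario for property tests
small_scenario <- function(seed, n = 600L, ...) {
  scenario_config(n_patients = n, n_practices = 20L, seed = seed, ...)
}

## ---- independent oracles ------------------------------------------------

## day-resolution exposure classifier: current iff the day lies in any
## prescription's [rx, rx+91) window; otherwise classify from the most
## recent prior prescription.  Window-membership matrices, independent of
## the package's findInterval route.
oracle_classify_days <- function(rx_days, days) {
  if (!length(rx_days)) return(rep("never", length(days)))
  in_window <- outer(rx_days, days, function(r, d) d >= r & d < r + 91)
  cur <- colSums(in_window) > 0
  prior <- outer(rx_days, days, function(r, d) ifelse(r <= d, r, -Inf))
  last_prior <- apply(prior, 2, max)
  gap <- days - last_prior
  ifelse(cur, "current",
         ifelse(!is.finite(last_prior), "never",
                ifelse(gap < 365, "recent", "past")))
}

## brute-force Kaplan-Meier by risk-set products (ties: events first)
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.table(time = ts, surv = surv)
}

## Poisson log-likelihood for a cell table with columns events, py and a
## design matrix; maximised derivative-free (Nelder-Mead)
oracle_poisson_fit <- function(X, events, py, start = NULL) {
  nll <- function(beta) {
    mu <- exp(X %*% beta + log(py))
    -sum(events * log(mu) - mu)
  }
  start <- start %||% rep(0, ncol(X))
  fit <- optim(start, nll, method = "Nelder-Mead",
               control = list(maxit = 50000, reltol = 1e-14))
  fit2 <- optim(fit$par, nll, method = "Nelder-Mead",
                control = list(maxit = 50000, reltol = 1e-14))
  fit2$par
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## analytic person-time of a spell set on an equal-width grid, by day loop
oracle_grid_person_time <- function(durations, n_periods) {
  width <- max(durations) / n_periods
  pt <- numeric(n_periods)
  for (d in durations) {
    full_days <- seq_len(ceiling(d)) - 1L
    for (day in full_days) {
      amt <- min(d - day, 1)
      a <- day; b <- day + amt
      for (p in seq_len(n_periods)) {
        lo <- (p - 1) * width; hi <- p * width
        ov <- min(b, hi) - max(a, lo)
        if (ov > 0) pt[p] <- pt[p] + ov
      }
    }
  }
  pt
}

## one moderate synthetic study reused by the orchestrator tests
study_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ## a thiazolidinedione-heavy, fully linked scenario inside the
      ## death-certificate window, so cause-specific death counts are
      ## informative at test scale
      rates <- default_initiation_rates()
      rates$rosiglitazone <- list(base = 0.05, multipliers = numeric(0))
      rates$pioglitazone <- list(base = 0.05, multipliers = numeric(0))
      hz <- default_outcome_hazards()
      hz$death["base"] <- 0.025
      cfg <- scenario_config(
        n_patients = 20000L, n_practices = 100L, seed = 71L,
        calendar_start = "2001-01-01", calendar_end = "2009-12-31",
        linkage_fraction = 1,
        class_initiation_rates = rates,
        outcome_baseline_hazards = hz,
        persistence = c(metformin = 0.25, sulphonylurea = 0.3,
                        rosiglitazone = 0.1, pioglitazone = 0.1,
                        insulin = 0.15, other_oad = 0.4),
        cause_of_death_mix = list(
          rosiglitazone = c(circulatory = 0.6, neoplasm = 0.25,
                            respiratory = 0.15),
          pioglitazone = c(circulatory = 0.2, neoplasm = 0.55,
                           respiratory = 0.25),
          none = c(circulatory = 0.4, neoplasm = 0.4,
                   respiratory = 0.2)),
        true_log_rr = numeric(0))
      tabs <- simulate_ehr(cfg)
      setattr(tabs, "config", cfg)
      cache <<- list(cfg = cfg, tabs = tabs)
    }
    cache
  }
})

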