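## Synthetic primary-care EHR generator.
##
## Event times are drawn from competing piecewise-constant hazards by exact
## inversion within each constant piece, so rate-calibration tests are
## sharp (no discretisation error).  All randomness is governed by
## deterministic sub-seeds of the scenario seed.

#' Generate the synthetic patient population
#'
#' Creates patients clustered in practices with demographics, observation
#' windows, a hidden standard-normal severity score (the confounder that
#' drives channeling and outcome hazards), a type-1 diabetes exclusion
#' flag, and the practice-level linkage flags that gate hospital and
#' death-certificate data.
#'
#' The returned patient table carries `latent_severity` so that downstream
#' generator stages can use it; [simulate_ehr()] writes it only to the
#' ground-truth sidecar, never to `patients.csv`, and no analysis module
#' reads it.
#'
#' @param config A [scenario_config()].
#' @return A list with `patients` (one row per patient), `practices`
#'   (practice_id, linked, ses_quintile) and `ground_truth` (the latent
#'   draws needed to recompute each patient's hazard trajectory).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(sub_seed(config$seed, 0L))
  n <- config$n_patients
  np <- config$n_practices

  practices <- data.table(
    practice_id = seq_len(np),
    linked = runif(np) < config$linkage_fraction,
    ses_quintile = sample(1:5, np, replace = TRUE)
  )

  ## truncated-normal age at data_start on [40, 95]
  lo <- pnorm(40, config$age_mean, config$age_sd)
  hi <- pnorm(95, config$age_mean, config$age_sd)
  age0 <- qnorm(runif(n, lo, hi), config$age_mean, config$age_sd)

  span_days <- as.numeric(config$calendar_end - config$calendar_start)
  ## leave at least a year of potential follow-up after data_start
  start_off <- floor(runif(n, 0, max(1, span_days - DAYS_PER_YEAR)))
  data_start <- config$calendar_start + start_off
  dur_years <- 0.5 + rexp(n, 1 / config$follow_up_mean_years)
  data_end <- pmin(config$calendar_end,
                   data_start + ceiling(dur_years * DAYS_PER_YEAR))

  patients <- data.table(
    patient_id = seq_len(n),
    practice_id = sample(np, n, replace = TRUE),
    sex = ifelse(runif(n) < config$sex_male, "M", "F"),
    birth_year = year_of(data_start) - floor(age0),
    data_start = data_start,
    data_end = data_end,
    type1 = runif(n) < config$type1_fraction,
    latent_severity = rnorm(n),
    death_date = as.Date(NA),
    death_source = ""
  )
  patients <- practices[patients, on = "practice_id"]
  setcolorder(patients, c("patient_id", "practice_id", "linked",
                          "ses_quintile"))
  ground_truth <- patients[, .(patient_id, latent_severity)]
  list(patients = patients, practices = practices,
       ground_truth = ground_truth)
}

## Exact inversion of a piecewise-constant hazard.
## pieces: data.table(patient_id, t0, t1, rate) ordered by (patient_id, t0)
## with t0/t1 numeric days and rate per person-year; E named by patient_id.
## Returns data.table(patient_id, time) for patients whose draw lands
## inside their window (numeric days, continuous).
draw_from_pieces <- function(pieces, E) {
  if (!nrow(pieces)) return(data.table(patient_id = integer(0), time = numeric(0)))
  p <- copy(pieces)
  setorder(p, patient_id, t0)
  p[, inc := rate * (t1 - t0) / DAYS_PER_YEAR]
  p[, c_end := cumsum(inc), by = patient_id]
  p[, c_start := c_end - inc]
  p[, e := E[as.character(patient_id)]]
  hit <- p[e > c_start & e <= c_end & rate > 0]
  hit[, time := t0 + (e - c_start) / rate * DAYS_PER_YEAR]
  hit[, .(patient_id, time)]
}

## Per-patient, per-class first initiation of a drug class under a
## calendar-varying hazard; returns Date or NA.
draw_initiation <- function(patients, cls_cfg, channel_mult) {
  n <- nrow(patients)
  E <- rexp(n)
  names(E) <- as.character(patients$patient_id)
  yrs <- seq(year_of(min(patients$data_start)),
             year_of(max(patients$data_end)))
  mult <- rep(1, length(yrs)); names(mult) <- as.character(yrs)
  if (length(cls_cfg$multipliers)) {
    hit <- intersect(names(cls_cfg$multipliers), names(mult))
    mult[hit] <- cls_cfg$multipliers[hit]
  }
  pieces <- rbindlist(lapply(yrs, function(y) {
    y0 <- as.numeric(as.Date(sprintf("%d-01-01", y)))
    y1 <- as.numeric(as.Date(sprintf("%d-01-01", y + 1L)))
    t0 <- pmax(as.numeric(patients$data_start), y0)
    t1 <- pmin(as.numeric(patients$data_end), y1)
    keep <- t1 > t0
    data.table(patient_id = patients$patient_id[keep],
               t0 = t0[keep], t1 = t1[keep],
               rate = cls_cfg$base * mult[[as.character(y)]] *
                 channel_mult[keep])
  }))
  hit <- draw_from_pieces(pieces, E)
  out <- data.table(patient_id = patients$patient_id,
                    init = as.Date(NA), E_init = E)
  out[hit, init := as.Date(floor(i.time), origin = "1970-01-01"),
      on = "patient_id"]
  out
}

#' Generate prescription streams
#'
#' For each patient and drug class, a first-initiation time is drawn from
#' the class's baseline initiation hazard times the calendar-year
#' multiplier, times `exp(channeling_strength * severity)` for channelled
#' classes.  After initiation, repeat prescriptions are issued every
#' `prescription_cycle` days until a discontinuation time drawn from the
#' per-class persistence hazard (or end of observation).  A fraction of
#' thiazolidinedione prescriptions are multi-constituent combinations with
#' metformin.
#'
#' @param patients Patient table from [generate_population()] (must carry
#'   `latent_severity`).
#' @param config The [scenario_config()].
#' @return A `data.table` of prescriptions (patient_id, date, drug_class,
#'   multi_constituent), sorted by patient and date, with attributes
#'   `initiation_summary` (initiations by class and calendar year) and
#'   `rx_truth` (per-class latent draws).
#' @export
generate_prescriptions <- function(patients, config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(sub_seed(config$seed, 1L))
  cycle <- config$prescription_cycle

  rx_list <- list()
  truth <- data.table(patient_id = patients$patient_id)
  for (cl in drug_classes()) {
    cls_cfg <- config$class_initiation_rates[[cl]]
    channel_mult <- if (cl %in% config$channelled_classes)
      exp(config$channeling_strength * patients$latent_severity)
    else rep(1, nrow(patients))
    ini <- draw_initiation(patients, cls_cfg, channel_mult)
    stop_years <- rexp(nrow(patients),
                       rate = pmax(config$persistence[[cl]], 1e-12))
    truth[, (paste0("E_init_", cl)) := ini$E_init]
    truth[, (paste0("stop_years_", cl)) := stop_years]
    started <- !is.na(ini$init)
    if (!any(started)) next
    idx <- which(started)
    init <- as.numeric(ini$init[idx])
    last_day <- pmin(as.numeric(patients$data_end[idx]) - 1,
                     init + stop_years[idx] * DAYS_PER_YEAR)
    n_rx <- pmax(0L, floor((last_day - init) / cycle)) + 1L
    rx <- data.table(
      patient_id = rep(patients$patient_id[idx], n_rx),
      date = as.Date(rep(init, n_rx) + sequence(n_rx, from = 0L) * cycle,
                     origin = "1970-01-01"),
      drug_class = cl
    )
    rx_list[[cl]] <- rx
  }
  rx <- rbindlist(rx_list)
  rx[, multi_constituent := NA_character_]
  tzd <- rx$drug_class %in% tzd_classes()
  combo <- tzd & runif(nrow(rx)) < config$multi_constituent_prob
  rx[combo, multi_constituent := "metformin"]
  setorder(rx, patient_id, date, drug_class)

  first_rx <- rx[, .(date = min(date)), by = .(patient_id, drug_class)]
  summary <- first_rx[, .N, by = .(drug_class, year = year_of(date))]
  setorder(summary, drug_class, year)
  setattr(rx, "initiation_summary", summary)
  setattr(rx, "rx_truth", truth)
  rx[]
}

## log hazard-multiplier intervals (current / recent-past) for the classes
## that carry true effects; built on the same window rules as the exposure
## module (current_episodes()).
exposure_effect_pieces <- function(rx, classes_needed) {
  if (!length(classes_needed))
    return(data.table(patient_id = integer(0), drug_class = character(0),
                      t0 = numeric(0), t1 = numeric(0),
                      phase = character(0)))
  rxe <- expand_rx(rx)[drug_class %in% classes_needed]
  ep <- current_episodes(rxe)
  if (!nrow(ep))
    return(data.table(patient_id = integer(0), drug_class = character(0),
                      t0 = numeric(0), t1 = numeric(0),
                      phase = character(0)))
  ep[, next_start := shift(as.numeric(first_rx), type = "lead",
                           fill = Inf), by = .(patient_id, drug_class)]
  cur <- ep[, .(patient_id, drug_class,
                t0 = as.numeric(first_rx),
                t1 = as.numeric(last_rx) + CURRENT_WINDOW_DAYS,
                phase = "current")]
  post <- ep[, .(patient_id, drug_class,
                 t0 = as.numeric(last_rx) + CURRENT_WINDOW_DAYS,
                 t1 = next_start, phase = "recent_past")]
  rbind(cur, post[t1 > t0])
}

#' Generate clinical outcomes, deaths and death causes
#'
#' Event times are drawn outcome by outcome from piecewise-constant
#' hazards: the outcome's baseline hazard times log-linear age, sex and
#' severity terms, times `exp(true_log_rr[class, outcome])` while the
#' patient is current on the class (and `recent_past_log_rr` after
#' discontinuation).  Current-use windows follow the same 91-day rule as
#' the exposure-history module.  Death truncates all other outcomes.
#' Deaths are assigned a primary ICD-10 cause from the configured mix of
#' the current drug class at death; death-certificate causes and hospital
#' event records exist only for linked practices inside the respective
#' collection windows.
#'
#' @param patients,prescriptions Output of the previous generator stages.
#' @param config The [scenario_config()].
#' @return List with `patients` (death date/source filled in), `events`
#'   (clinical events with GP/hospital source rows), `death_causes`
#'   (patient_id, icd10_code) and `event_truth` (the exponential draws).
#' @export
generate_outcomes <- function(patients, prescriptions, config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(sub_seed(config$seed, 2L))
  patients <- copy(patients)
  n <- nrow(patients)

  eff_names <- unique(c(names(config$true_log_rr),
                        names(config$recent_past_log_rr)))
  eff_classes <- if (length(eff_names))
    unique(vapply(strsplit(eff_names, ":", fixed = TRUE), `[`, "", 1L))
  else character(0)
  eff <- exposure_effect_pieces(prescriptions, eff_classes)

  ## base cuts: observation window split at calendar-year boundaries so
  ## the age term moves with calendar time
  yr_range <- (year_of(min(patients$data_start))):(year_of(max(patients$data_end)) + 1L)
  ylk <- year_lookup(yr_range)
  wb <- patients[, .(patient_id, y0 = year_of(data_start) + 1L,
                     y1 = year_of(data_end - 1L))][y1 >= y0]
  ycuts <- if (nrow(wb)) {
    nrep <- wb$y1 - wb$y0 + 1L
    data.table(patient_id = rep(wb$patient_id, nrep),
               cut = ylk[as.character(sequence(nrep, from = wb$y0))])
  } else data.table(patient_id = integer(0), cut = numeric(0))
  cuts <- rbind(
    patients[, .(patient_id, cut = as.numeric(data_start))],
    patients[, .(patient_id, cut = as.numeric(data_end))],
    ycuts,
    eff[, .(patient_id, cut = t0)],
    eff[, .(patient_id, cut = t1)])
  cuts <- unique(cuts)
  win <- patients[, .(patient_id, w0 = as.numeric(data_start),
                      w1 = as.numeric(data_end))]
  cuts <- win[cuts, on = "patient_id"][cut >= w0 & cut <= w1]
  setorder(cuts, patient_id, cut)
  pieces <- cuts[, .(t0 = cut[-.N], t1 = cut[-1]), by = patient_id]
  pieces <- pieces[t1 > t0]

  ## per-piece attributes
  pieces <- patients[, .(patient_id, birth_year, sex,
                         sev = latent_severity)][pieces, on = "patient_id"]
  byrs <- sort(unique(patients$birth_year))
  dobl <- setNames(as.numeric(as.Date(sprintf("%d-07-01", byrs))),
                   as.character(byrs))
  pieces[, age := floor((t0 - dobl[as.character(birth_year)]) /
                          DAYS_PER_YEAR)]
  for (cl in eff_classes) {
    for (ph in c("current", "recent_past")) {
      cl_eff <- eff[drug_class == cl & phase == ph]
      flag <- paste0(ph, "_", cl)
      pieces[, (flag) := FALSE]
      if (nrow(cl_eff)) {
        hit <- cl_eff[pieces, on = .(patient_id, t0 <= t0, t1 > t0),
                      which = TRUE, mult = "first"]
        pieces[!is.na(hit), (flag) := TRUE]
      }
    }
  }

  outcome_rate <- function(outc) {
    hz <- config$outcome_baseline_hazards[[outc]]
    lr <- log(hz[["base"]]) +
      hz[["log_hr_age10"]] * (pieces$age - 65) / 10 +
      hz[["log_hr_male"]] * (pieces$sex == "M") +
      hz[["log_hr_severity"]] * pieces$sev
    lk <- function(v, k) if (k %in% names(v)) v[[k]] else 0
    for (cl in eff_classes) {
      k <- paste(cl, outc, sep = ":")
      if (lk(config$true_log_rr, k) != 0)
        lr <- lr + lk(config$true_log_rr, k) *
          pieces[[paste0("current_", cl)]]
      if (lk(config$recent_past_log_rr, k) != 0)
        lr <- lr + lk(config$recent_past_log_rr, k) *
          pieces[[paste0("recent_past_", cl)]]
    }
    exp(lr)
  }

  event_truth <- data.table(patient_id = patients$patient_id)

  ## death first: it truncates everything else
  E_death <- rexp(n); names(E_death) <- as.character(patients$patient_id)
  event_truth[, E_death := E_death]
  dp <- copy(pieces)[, rate := outcome_rate("death")]
  hit <- draw_from_pieces(dp[, .(patient_id, t0, t1, rate)], E_death)
  patients[hit, death_date := as.Date(floor(i.time), origin = "1970-01-01"),
           on = "patient_id"]
  patients[!is.na(death_date),
           death_source := ifelse(linked & death_date >= config$ons_start,
                                  "gp;cert", "gp")]

  ## follow-up end for non-fatal outcomes: day after death or data_end
  fup_end <- as.numeric(patients$data_end)
  dd <- as.numeric(patients$death_date)
  fup_end <- ifelse(!is.na(dd), pmin(fup_end, dd + 1), fup_end)
  names(fup_end) <- as.character(patients$patient_id)

  ev_list <- list()
  for (outc in setdiff(study_outcomes(), "death")) {
    E <- rexp(n); names(E) <- as.character(patients$patient_id)
    event_truth[, (paste0("E_", outc)) := E]
    op <- copy(pieces)[, rate := outcome_rate(outc)]
    op[, t1 := pmin(t1, fup_end[as.character(patient_id)])]
    op <- op[t1 > t0]
    hit <- draw_from_pieces(op[, .(patient_id, t0, t1, rate)], E)
    if (nrow(hit))
      ev_list[[outc]] <- hit[, .(patient_id,
                                 date = as.Date(floor(time),
                                                origin = "1970-01-01"),
                                 outcome = outc)]
  }
  ev <- rbindlist(ev_list)
  events <- data.table(patient_id = integer(0), date = as.Date(character(0)),
                       outcome = character(0), source = character(0))
  if (nrow(ev)) {
    ev <- patients[, .(patient_id, linked)][ev, on = "patient_id"]
    u_gp <- runif(nrow(ev)); u_hes <- runif(nrow(ev))
    gp_rows <- ev[u_gp < config$gp_capture,
                  .(patient_id, date, outcome, source = "gp")]
    hes_rows <- ev[linked & date >= config$hes_start &
                     u_hes < config$hospital_capture,
                   .(patient_id, date, outcome, source = "hospital")]
    events <- rbind(gp_rows, hes_rows)
    setorder(events, patient_id, date, outcome, source)
  }

  death_causes <- assign_death_causes(patients, prescriptions, config)

  list(patients = patients, events = events, death_causes = death_causes,
       event_truth = event_truth)
}

## ICD-10 codes representative of each configured chapter key; circulatory
## deaths are further split into ischemic / heart-failure / other.
chapter_code_pool <- function() {
  list(infectious = "A41.9", neoplasm = "C34.9", endocrine = "E11.9",
       mental = "F03", nervous = "G30.9",
       circulatory = c("I21.9", "I50.0", "I64"),
       respiratory = "J18.9", digestive = "K92.9", skin = "L97",
       musculoskeletal = "M06.9", genitourinary = "N18.9",
       external = "X59.9", other = "R99")
}

assign_death_causes <- function(patients, prescriptions, config) {
  dead <- patients[!is.na(death_date) & grepl("cert", death_source)]
  if (!nrow(dead))
    return(data.table(patient_id = integer(0), icd10_code = character(0)))
  ## current class at death among the classes with a configured mix
  mix_classes <- setdiff(names(config$cause_of_death_mix), "none")
  cls_at_death <- rep("none", nrow(dead))
  rxe <- expand_rx(prescriptions)
  for (cl in mix_classes) {
    cl_rx <- rxe[drug_class == cl]
    if (!nrow(cl_rx)) next
    st <- classify_exposure_at(cl_rx, dead$patient_id, dead$death_date)
    cls_at_death[st == "current" & cls_at_death == "none"] <- cl
  }
  pool <- chapter_code_pool()
  codes <- character(nrow(dead))
  for (cl in unique(cls_at_death)) {
    idx <- which(cls_at_death == cl)
    mix <- config$cause_of_death_mix[[cl]] %||%
      config$cause_of_death_mix[["none"]]
    chap <- sample(names(mix), length(idx), replace = TRUE, prob = mix)
    codes[idx] <- vapply(chap, function(ch) {
      p <- pool[[ch]]
      if (length(p) == 1L) p else sample(p, 1L, prob = c(0.65, 0.2, 0.15))
    }, "")
  }
  data.table(patient_id = dead$patient_id, icd10_code = codes)
}

#' Generate covariate records
#'
#' Baseline lifestyle values (smoking, alcohol, BMI; a configurable
#' fraction missing), comorbidity-history flags whose prevalence rises
#' with severity and age, the practice-level socioeconomic quintile, and
#' dated co-medication records (repeat records every 150 days while the
#' patient persists, so a 183-day lookback sees them).
#'
#' @param patients Patient table (with `latent_severity`).
#' @param config The [scenario_config()].
#' @return Long `data.table` (patient_id, date, covariate, value).
#' @export
generate_covariates <- function(patients, config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(sub_seed(config$seed, 3L))
  n <- nrow(patients)
  sev <- patients$latent_severity
  age0 <- age_at(patients$birth_year, patients$data_start)
  miss <- function(x) {
    x[runif(length(x)) < config$missing_covariate_fraction] <- NA
    x
  }
  base <- function(name, value) {
    data.table(patient_id = patients$patient_id, date = patients$data_start,
               covariate = name, value = as.character(value))
  }
  plogis_ <- function(x) 1 / (1 + exp(-x))

  out <- list(
    base("smoking", miss(sample(c("non", "ex", "current"), n, TRUE,
                                prob = c(0.4, 0.4, 0.2)))),
    base("alcohol", miss(sample(c("none", "current"), n, TRUE,
                                prob = c(0.3, 0.7)))),
    base("bmi", miss(round(pmax(17, rnorm(n, 31, 6)), 1))),
    base("ses_quintile", patients$ses_quintile)
  )
  comorb <- c(chd = -2.1, revasc = -3.2, hyperlipidaemia = -2.3,
              hypertension = 0.85, pvd = -3.0, renal = -3.0, angina = -1.9)
  for (cm in names(comorb)) {
    p <- plogis_(comorb[[cm]] + 0.5 * sev + 0.03 * (age0 - 65))
    out[[length(out) + 1L]] <- base(paste0("com_", cm), as.integer(runif(n) < p))
  }
  comeds <- c(arb_acei = 0.45, antiplatelet = 0.40, beta_blocker = 0.24,
              ccb = 0.25, diuretic = 0.35, nitrate = 0.10, nsaid = 0.45,
              statin = 0.55)
  for (md in names(comeds)) {
    p <- plogis_(qnorm(comeds[[md]]) * 1.2 + 0.3 * sev)
    on_drug <- which(runif(n) < p)
    if (!length(on_drug)) next
    s <- as.numeric(patients$data_start[on_drug])
    e <- as.numeric(patients$data_end[on_drug])
    n_rec <- pmax(0L, floor((e - 1 - s) / 150)) + 1L
    out[[length(out) + 1L]] <- data.table(
      patient_id = rep(patients$patient_id[on_drug], n_rec),
      date = as.Date(rep(s, n_rec) + sequence(n_rec, from = 0L) * 150,
                     origin = "1970-01-01"),
      covariate = paste0("rx6m_", md),
      value = "1")
  }
  cov <- rbindlist(out)
  setorder(cov, patient_id, date, covariate)
  cov[]
}

#' Run the full synthetic EHR generator
#'
#' Chains [generate_population()], [generate_prescriptions()],
#' [generate_covariates()] and [generate_outcomes()], and optionally
#' writes the five analysis tables plus the ground-truth sidecar and a
#' run manifest as comma-separated text with ISO-8601 dates.
#'
#' @param config A [scenario_config()].
#' @param out_dir Optional directory; when given, writes patients.csv,
#'   prescriptions.csv, events.csv, death_causes.csv, covariates.csv,
#'   ground_truth.csv and manifest.yaml (falls back to manifest.dcf when
#'   the yaml package is unavailable).
#' @return Invisibly, a list of tables: patients (without the latent
#'   severity column), practices, prescriptions, events, death_causes,
#'   covariates, ground_truth.
#' @export
simulate_ehr <- function(config, out_dir = NULL) {
  pop <- generate_population(config)
  rx <- generate_prescriptions(pop$patients, config)
  cov <- generate_covariates(pop$patients, config)
  oc <- generate_outcomes(pop$patients, rx, config)

  ground_truth <- merge(
    merge(pop$ground_truth, attr(rx, "rx_truth"), by = "patient_id"),
    oc$event_truth, by = "patient_id")
  patients_out <- copy(oc$patients)[, latent_severity := NULL]

  tables <- list(patients = patients_out, practices = pop$practices,
                 prescriptions = rx, events = oc$events,
                 death_causes = oc$death_causes, covariates = cov,
                 ground_truth = ground_truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("patients", "prescriptions", "events", "death_causes",
                 "covariates", "ground_truth")) {
      fwrite(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
             dateTimeAs = "ISO")
    }
    write_manifest(config, out_dir)
  }
  invisible(tables)
}

write_manifest <- function(config, out_dir) {
  m <- lapply(unclass(config), function(x) {
    if (inherits(x, "Date")) format(x) else x
  })
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(m, file.path(out_dir, "manifest.yaml"))
  } else {
    flat <- vapply(m, function(x) paste(deparse(x), collapse = " "), "")
    writeLines(paste0(names(flat), ": ", flat),
               file.path(out_dir, "manifest.dcf"))
  }
  invisible(NULL)
}
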