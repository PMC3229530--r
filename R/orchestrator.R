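## End-to-end study orchestration: the four analysis sets (past-use bias
## analysis, current-use comparison, duration-of-use curves, life tables)
## plus the cause-of-death table, and deterministic report rendering.

## ---------------------------------------------------------------------
## ICD-10 chapter mapping
## ---------------------------------------------------------------------

icd10_chapters <- function() {
  data.table(
    chapter = c("infectious", "neoplasm", "endocrine", "mental",
                "nervous", "circulatory", "respiratory", "digestive",
                "skin", "musculoskeletal", "genitourinary", "external"),
    label = c("A00-B99: Certain infectious and parasitic diseases",
              "C00-D89: Neoplasms/Diseases of the blood",
              "E00-E90: Endocrine, nutritional and metabolic disorders",
              "F00-F99: Mental and behavioural disorders",
              "G00-G99: Diseases of the nervous system",
              "I00-I99: Diseases of the circulatory system",
              "J00-J99: Diseases of the respiratory system",
              "K00-K93: Diseases of the digestive system",
              "L00-L99: Diseases of the skin and subcutaneous tissue",
              "M00-M99: Diseases of the musculoskeletal system",
              "N00-N99: Diseases of the genitourinary system",
              "V01-Y98: External causes of morbidity and mortality"),
    from = c("A00", "C00", "E00", "F00", "G00", "I00", "J00", "K00",
             "L00", "M00", "N00", "V01"),
    to = c("B99", "D89", "E90", "F99", "G99", "I99", "J99", "K93",
           "L99", "M99", "N99", "Y98")
  )
}

#' Map ICD-10 codes to cause-of-death chapters
#'
#' Assigns each code to one of the chapter ranges A00-B99, C00-D89,
#' E00-E90, F00-F99, G00-G99, I00-I99, J00-J99, K00-K93, L00-L99,
#' M00-M99, N00-N99, V01-Y98; codes in I20-I25 (ischemic heart disease)
#' and I50 (heart failure) are additionally flagged.  Unparseable or
#' out-of-range codes map to `"unclassified"`.
#'
#' @param code Character vector of ICD-10 codes (e.g. `"I21.4"`).
#' @return `data.table` with `code`, `chapter`, `ischemic`,
#'   `heart_failure`.
#' @examples
#' map_icd10_chapter(c("I21.4", "J18", ""))
#' @export
map_icd10_chapter <- function(code) {
  ch <- icd10_chapters()
  key <- toupper(sub("^([A-Za-z][0-9]{2}).*", "\\1",
                     trimws(as.character(code))))
  valid <- grepl("^[A-Z][0-9]{2}$", key)
  chapter <- rep("unclassified", length(code))
  for (i in seq_len(nrow(ch))) {
    hit <- valid & key >= ch$from[i] & key <= ch$to[i]
    chapter[hit] <- ch$chapter[i]
  }
  data.table(code = as.character(code), chapter = chapter,
             ischemic = valid & key >= "I20" & key <= "I25",
             heart_failure = valid & key == "I50")
}

## ---------------------------------------------------------------------
## shared plumbing
## ---------------------------------------------------------------------

## death "events" table from the patient file, optionally restricted to a
## recording source
death_events <- function(patients, source = c("gp", "cert")) {
  source <- match.arg(source)
  pat <- as.data.table(patients)
  d <- pat[!is.na(death_date)]
  if (source == "cert") d <- d[grepl("cert", death_source)]
  d[, .(patient_id, date = death_date)]
}

outcome_events <- function(tables, outcome, source) {
  if (outcome == "death")
    death_events(tables$patients, if (source == "cert") "cert" else "gp")
  else {
    o <- outcome; s <- source
    as.data.table(tables$events)[outcome == o & source == s,
                                 .(patient_id, date, outcome)]
  }
}

## restrict person-time to linked practices inside a linkage window
restrict_linked <- function(segments, patients, window_start) {
  linked_ids <- as.data.table(patients)[(linked), patient_id]
  seg <- as.data.table(segments)[patient_id %in% linked_ids &
                                   start >= window_start]
  finish_person_time(copy(seg))
}

rr_row <- function(fit, lvl) {
  if (inherits(fit, "not_estimable"))
    return(data.table(RR = NA_real_, lower = NA_real_, upper = NA_real_))
  t <- fit$terms[fit$terms$level == lvl]
  data.table(RR = t$RR, lower = t$lower, upper = t$upper)
}

## ---------------------------------------------------------------------
## analysis set 1: past-use bias analysis
## ---------------------------------------------------------------------

#' Past-use (negative control) bias analysis
#'
#' Compares outcome rates during past exposure of each drug class against
#' (a) matched non-diabetic controls and (b) past metformin exposure,
#' minimally and fully adjusted.  Because past users have discontinued
#' the drug more than a year earlier, persistent rate differences signal
#' residual confounding by the underlying disease (or persistent drug
#' effects); the `residual_confounding` flag marks contrasts whose fully
#' adjusted rate ratio confidence interval excludes 1.
#'
#' @param tables Generator tables (patients, prescriptions, events,
#'   covariates).
#' @param cohorts List with `overall` (exposed cohort entries) and
#'   `controls` (matched control entries), e.g. from [run_study()]'s
#'   cohort step.
#' @param classes Drug classes to contrast (default all but metformin and
#'   other oral antidiabetics).
#' @param outcomes Outcomes to analyse (GP-recorded).
#' @return `data.table` with one row per (outcome, class, comparison,
#'   adjustment): events, person-years, RR, CI, residual-confounding
#'   flag; `not-estimable` rows carry NA.
#' @export
run_bias_analysis <- function(tables, cohorts,
                              classes = c("insulin", "sulphonylurea",
                                          "rosiglitazone", "pioglitazone"),
                              outcomes = study_outcomes()) {
  seg_exp <- split_person_time(cohorts$overall, tables$patients,
                               tables$prescriptions, tables$covariates)
  has_controls <- !is.null(cohorts$controls) && nrow(cohorts$controls) > 0
  seg_ctl <- if (has_controls)
    split_person_time(cohorts$controls, tables$patients,
                      tables$prescriptions, tables$covariates)
  rows <- list()
  for (outc in outcomes) {
    ev <- outcome_events(tables, outc, "gp")
    a_exp <- attribute_events(seg_exp, ev, outcome = outc)
    a_ctl <- if (has_controls) {
      ac <- attribute_events(seg_ctl, ev, outcome = outc)
      ac[, exposure := "control"]
      ac
    }
    for (cl in classes) {
      past <- a_exp[a_exp[[paste0("state_", cl)]] == "past"]
      past[, exposure := paste0("past_", cl)]
      for (adj in c("minimal", "full")) {
        ## vs matched controls
        fit_c <- if (!has_controls || !nrow(past)) not_estimable("no data")
        else tryCatch(
          fit_rate_model(rbind(a_ctl, past, fill = TRUE)[
            , exposure := factor(exposure,
                                 levels = c("control", paste0("past_", cl)))],
            adjustment = adj, exclude_classes = cl),
          error = function(e) not_estimable(conditionMessage(e)))
        rows[[length(rows) + 1L]] <- data.table(
          outcome = outc, drug_class = cl, comparison = "control",
          adjustment = adj,
          events = sum(past$events), person_years = sum(past$py),
          rr_row(fit_c, paste0("past_", cl)))
        ## vs past metformin
        fit_m <- if (cl == "metformin") not_estimable("is reference")
        else tryCatch({
          pm <- past_use_contrast(a_exp, cl, "metformin")
          fit_rate_model(pm, adjustment = adj,
                         exclude_classes = c(cl, "metformin"))
        }, error = function(e) not_estimable(conditionMessage(e)))
        rows[[length(rows) + 1L]] <- data.table(
          outcome = outc, drug_class = cl, comparison = "past_metformin",
          adjustment = adj,
          events = sum(past$events), person_years = sum(past$py),
          rr_row(fit_m, cl))
      }
    }
  }
  out <- rbindlist(rows)
  out[, residual_confounding := adjustment == "full" & !is.na(lower) &
        (lower > 1 | upper < 1)]
  out[]
}

#' Past-use comparability gate for a within-class contrast
#'
#' Operationalises the rule that current-use comparisons are restricted
#' to drugs without major past-use rate differences: the fully adjusted
#' past-use rate ratio of `drug_class` versus `reference` for the gate
#' outcome (death) must have a confidence interval covering 1 within the
#' configured tolerance.
#'
#' @param tables,cohorts As in [run_bias_analysis()].
#' @param drug_class,reference The two classes of the intended contrast.
#' @param outcome Gate outcome (default death).
#' @param tolerance The CI must overlap `[1/tolerance, tolerance]`.
#' @return List with `passed`, `RR`, `lower`, `upper`, `outcome`.
#' @export
bias_gate <- function(tables, cohorts, drug_class = "rosiglitazone",
                      reference = "pioglitazone", outcome = "death",
                      tolerance = 1) {
  seg <- split_person_time(cohorts$overall, tables$patients,
                           tables$prescriptions, tables$covariates)
  a <- attribute_events(seg, outcome_events(tables, outcome, "gp"),
                        outcome = outcome)
  pm <- past_use_contrast(a, drug_class, reference)
  fit <- tryCatch(
    fit_rate_model(pm, adjustment = "full",
                   exclude_classes = c(drug_class, reference)),
    error = function(e) not_estimable(conditionMessage(e)))
  r <- rr_row(fit, drug_class)
  passed <- !is.na(r$RR) && r$lower <= tolerance && r$upper >= 1 / tolerance
  list(passed = isTRUE(passed), RR = r$RR, lower = r$lower,
       upper = r$upper, outcome = outcome, drug_class = drug_class,
       reference = reference)
}

## ---------------------------------------------------------------------
## analysis set 2: current-use comparison
## ---------------------------------------------------------------------

## person-time for a head-to-head current-use contrast: each class's
## inception cohort censored at the first prescription of the comparator
contrast_person_time <- function(tables, drug_class, reference) {
  coh_a <- build_inception_cohort(tables$patients, tables$prescriptions,
                                  drug_class)
  coh_b <- build_inception_cohort(tables$patients, tables$prescriptions,
                                  reference)
  seg_a <- split_person_time(coh_a, tables$patients, tables$prescriptions,
                             tables$covariates, reference_class = reference)
  seg_b <- split_person_time(coh_b, tables$patients, tables$prescriptions,
                             tables$covariates, reference_class = drug_class)
  ## re-number entries so the two cohorts do not collide
  seg_b[, entry := entry + max(seg_a$entry)]
  finish_person_time(rbind(seg_a, seg_b))
}

#' Current-use comparison between two drug classes
#'
#' Rates of each outcome during current use of `drug_class` versus
#' `reference`, per data source, with minimal and full adjustment, plus
#' the stratified analyses (age, insulin co-prescribing, calendar time
#' before/from 2007).  Analyses using hospital or death-certificate data
#' are restricted to linked practices inside the respective collection
#' window.  The past-use comparability gate verdict is recorded with the
#' results; a failing gate flags the report rather than suppressing it.
#'
#' @param tables Generator tables.
#' @param drug_class,reference Contrast classes (default rosiglitazone
#'   vs pioglitazone).
#' @param gate Optional result of [bias_gate()].
#' @param outcomes Outcomes to analyse.
#' @return List with `main` (per outcome x source: events, rates, RRs),
#'   `stratified` (per outcome x stratum level), and `gate`.
#' @export
run_current_use_comparison <- function(tables,
                                       drug_class = "rosiglitazone",
                                       reference = "pioglitazone",
                                       gate = NULL,
                                       outcomes = study_outcomes()) {
  seg <- contrast_person_time(tables, drug_class, reference)
  cls <- c(drug_class, reference)
  sources <- function(outc)
    if (outc == "death") c("gp", "cert") else c("gp", "hospital")
  window_of <- function(src, cfg)
    if (src == "cert") cfg$ons_start else cfg$hes_start
  cfg <- attr(tables, "config")

  main <- list(); strat <- list()
  for (outc in outcomes) {
    for (src in sources(outc)) {
      seg_src <- if (src %in% c("cert", "hospital")) {
        ws <- if (!is.null(cfg)) window_of(src, cfg)
        else if (src == "cert") as.Date("2001-01-01") else as.Date("1997-04-01")
        restrict_linked(seg, tables$patients, ws)
      } else seg
      a <- tryCatch(
        attribute_events(seg_src, outcome_events(tables, outc, src),
                         outcome = outc),
        error = function(e) NULL)
      cu <- if (!is.null(a)) current_use_contrast(a, c(drug_class, reference),
                                                  reference = reference)
      for (adj in c("minimal", "full")) {
        fit <- if (is.null(cu) || !nrow(cu) || sum(cu$events) < 1L)
          not_estimable("no events in contrast person-time")
        else tryCatch(
          fit_rate_model(cu, adjustment = adj, exclude_classes = cls,
                         linked_only = src %in% c("cert", "hospital")),
          error = function(e) not_estimable(conditionMessage(e)))
        rates <- if (!is.null(cu) && nrow(cu))
          cu[, .(events = sum(events), person_years = sum(py)),
             by = .(level = exposure)]
        else data.table(level = factor(c(reference, drug_class)),
                        events = 0L, person_years = 0)
        rates[, rate := fifelse(person_years > 0,
                                100 * events / person_years, NA_real_)]
        main[[length(main) + 1L]] <- data.table(
          outcome = outc, source = src, adjustment = adj,
          rates[level == drug_class,
                .(events, person_years, rate)],
          ref_events = rates[level == reference, events],
          ref_person_years = rates[level == reference, person_years],
          ref_rate = rates[level == reference, rate],
          rr_row(fit, drug_class))
      }
      ## stratified analyses on the GP-recorded outcome
      if (src == "gp" && !is.null(cu) && nrow(cu)) {
        for (st in c("age65", "insulin", "calendar2007")) {
          for (adj in c("minimal", "full")) {
            fits <- run_stratified(cu, st, adjustment = adj,
                                   exclude_classes = cls)
            for (lv in names(fits)) {
              strat[[length(strat) + 1L]] <- data.table(
                outcome = outc, stratum = st, level = lv,
                adjustment = adj, rr_row(fits[[lv]], drug_class))
            }
          }
        }
      }
    }
  }
  list(main = rbindlist(main), stratified = rbindlist(strat),
       gate = gate, drug_class = drug_class, reference = reference)
}

## ---------------------------------------------------------------------
## cause of death
## ---------------------------------------------------------------------

#' Cause-of-death table for a current-use contrast
#'
#' All-cause and per-ICD-10-chapter mortality rates during current use of
#' two drug classes, over a shared person-time denominator restricted to
#' linked practices inside the death-certificate window, with minimally
#' adjusted rate ratios per chapter.
#'
#' @param tables Generator tables.
#' @param drug_class,reference Contrast classes.
#' @return `data.table`: one row for all-cause mortality, the twelve
#'   chapters and the ischemic (I20-I25) and heart-failure (I50)
#'   sub-ranges, with events and rates per arm and the adjusted RR.
#' @export
run_cause_of_death <- function(tables, drug_class = "rosiglitazone",
                               reference = "pioglitazone") {
  cfg <- attr(tables, "config")
  ons <- if (!is.null(cfg)) cfg$ons_start else as.Date("2001-01-01")
  seg <- contrast_person_time(tables, drug_class, reference)
  seg <- restrict_linked(seg, tables$patients, ons)
  a <- attribute_events(seg, death_events(tables$patients, "cert"),
                        outcome = "death")
  cu <- current_use_contrast(a, c(drug_class, reference),
                             reference = reference)
  if (!nrow(cu)) stop_config("no current-use person-time in the linked window")

  causes <- as.data.table(tables$death_causes)
  mp <- map_icd10_chapter(causes$icd10_code)
  causes[, `:=`(chapter = mp$chapter, ischemic = mp$ischemic,
                heart_failure = mp$heart_failure)]
  cu <- causes[cu, on = "patient_id"]
  cu[events == 0L, `:=`(chapter = NA_character_, ischemic = NA,
                        heart_failure = NA)]

  py_by <- cu[, .(person_years = sum(py)), by = .(level = exposure)]
  tally <- function(flag, label) {
    d <- copy(cu)[, events := as.integer(events == 1L & flag)]
    ev <- d[, .(events = sum(events)), by = .(level = exposure)]
    m <- merge(ev, py_by, by = "level")
    fit <- if (m[level == reference, events] == 0L ||
               sum(m$events) == 0L)
      not_estimable("no deaths in reference arm")
    else tryCatch(fit_rate_model(d, adjustment = "minimal",
                                 exclude_classes = c(drug_class, reference)),
                  error = function(e) not_estimable(conditionMessage(e)))
    data.table(cause = label,
               events = m[level == drug_class, events],
               rate = 100 * m[level == drug_class, events] /
                 m[level == drug_class, person_years],
               ref_events = m[level == reference, events],
               ref_rate = 100 * m[level == reference, events] /
                 m[level == reference, person_years],
               rr_row(fit, drug_class))
  }
  rows <- list(tally(TRUE, "all_cause"))
  for (ch in c(icd10_chapters()$chapter, "unclassified"))
    rows[[length(rows) + 1L]] <- tally(!is.na(cu$chapter) & cu$chapter == ch,
                                       ch)
  rows[[length(rows) + 1L]] <- tally(isTRUE_v(cu$ischemic), "I20-I25")
  rows[[length(rows) + 1L]] <- tally(isTRUE_v(cu$heart_failure), "I50")
  out <- rbindlist(rows)
  setattr(out, "person_years",
          setNames(py_by$person_years, as.character(py_by$level)))
  setattr(out, "class", c("cause_of_death_table", class(out)))
  out[]
}

isTRUE_v <- function(x) !is.na(x) & x

## ---------------------------------------------------------------------
## analysis sets 3 & 4: duration curves and life tables
## ---------------------------------------------------------------------

## per-arm spell tables for an outcome over the head-to-head person-time
contrast_spells <- function(tables, drug_class, reference, outcome,
                            source = "gp") {
  coh_a <- build_inception_cohort(tables$patients, tables$prescriptions,
                                  drug_class)
  coh_b <- build_inception_cohort(tables$patients, tables$prescriptions,
                                  reference)
  seg_a <- split_person_time(coh_a, tables$patients, tables$prescriptions,
                             reference_class = reference,
                             classes = c(drug_class, reference))
  seg_b <- split_person_time(coh_b, tables$patients, tables$prescriptions,
                             reference_class = drug_class,
                             classes = c(drug_class, reference))
  ev <- outcome_events(tables, outcome, source)
  a_a <- attribute_events(seg_a, ev, outcome = outcome)
  a_b <- attribute_events(seg_b, ev, outcome = outcome)
  list(current_use_spells(a_a, drug_class),
       current_use_spells(a_b, reference))
}

#' Smoothed hazard-ratio curve over duration of current use
#'
#' Builds the duration grid for each arm of a head-to-head contrast,
#' smooths both hazards with the same kernel and bandwidth on a common
#' grid, and returns the pointwise ratio curve.
#'
#' @param tables Generator tables.
#' @param drug_class,reference Contrast classes.
#' @param outcome Outcome (default death).
#' @param n_periods Number of duration periods (default 100).
#' @param bandwidth Kernel bandwidth in periods (default 10).
#' @param kernel Kernel name.
#' @return The [hazard_ratio_curve()] table, with the two
#'   `duration_grid`s as attributes.
#' @export
run_duration_analysis <- function(tables, drug_class = "rosiglitazone",
                                  reference = "pioglitazone",
                                  outcome = "death", n_periods = 100L,
                                  bandwidth = 10,
                                  kernel = "epanechnikov") {
  sp <- contrast_spells(tables, drug_class, reference, outcome)
  ## common grid span so the two hazards are evaluated at the same times
  maxd <- max(c(sp[[1]]$duration, sp[[2]]$duration))
  pad <- function(s) rbind(s, data.table(patient_id = NA_integer_,
                                         duration = maxd, event = 0L))
  g_a <- build_duration_grid(if (max(sp[[1]]$duration) < maxd)
    pad(sp[[1]]) else sp[[1]], n_periods)
  g_b <- build_duration_grid(if (max(sp[[2]]$duration) < maxd)
    pad(sp[[2]]) else sp[[2]], n_periods)
  h_a <- smooth_hazard(g_a, kernel = kernel, bandwidth = bandwidth)
  h_b <- smooth_hazard(g_b, kernel = kernel, bandwidth = bandwidth)
  out <- hazard_ratio_curve(h_a, h_b)
  setattr(out, "grid_num", g_a)
  setattr(out, "grid_den", g_b)
  out[]
}

#' Life-table report over current use
#'
#' Kaplan-Meier cumulative incidence (%) at one and three years for each
#' arm of a head-to-head contrast, overall and stratified by age band and
#' sex at index, with the excess risk (difference at full precision).
#' Includes the composite endpoint (first of death, ACS, stroke, heart
#' failure) when `composite = TRUE`.
#'
#' @param tables Generator tables.
#' @param drug_class,reference Contrast classes.
#' @param outcomes Outcomes to tabulate.
#' @param composite Also tabulate the composite endpoint.
#' @param horizons Horizons in days (default 1 and 3 years).
#' @return `data.table`: outcome x stratum x horizon with cumulative
#'   incidence and CI per arm and the excess risk.
#' @export
run_life_table_analysis <- function(tables,
                                    drug_class = "rosiglitazone",
                                    reference = "pioglitazone",
                                    outcomes = "death",
                                    composite = TRUE,
                                    horizons = c(365, 1095)) {
  pat <- as.data.table(tables$patients)
  spells_of <- lapply(setNames(nm = union(outcomes, if (composite)
    study_outcomes())), function(o)
      contrast_spells(tables, drug_class, reference, o))
  ## age/sex at index from the class's inception cohort
  coh <- rbind(build_inception_cohort(tables$patients, tables$prescriptions,
                                      drug_class),
               build_inception_cohort(tables$patients, tables$prescriptions,
                                      reference))
  coh <- pat[, .(patient_id, birth_year, sex)][coh, on = "patient_id"]
  coh[, age_band := age_band_of(age_at(birth_year, index_date))]
  strata_of <- coh[, .(patient_id, age_band, sex)]
  strata_of <- unique(strata_of, by = "patient_id")

  endpoints <- as.list(setNames(nm = outcomes))
  if (composite) endpoints$composite <- study_outcomes()

  rows <- list()
  for (ep in names(endpoints)) {
    arm_sp <- list()
    for (arm in 1:2) {
      eps <- endpoints[[ep]]
      if (length(eps) == 1L) arm_sp[[arm]] <- spells_of[[eps]][[arm]]
      else arm_sp[[arm]] <- do.call(composite_spells,
                                    lapply(eps, function(o)
                                      spells_of[[o]][[arm]]))
    }
    arm_sp <- lapply(arm_sp, function(s) strata_of[s, on = "patient_id"])
    add_rows <- function(sub_a, sub_b, stratum, level) {
      if (!nrow(sub_a) || !nrow(sub_b)) return(NULL)
      ci_a <- cumulative_incidence_at(
        kaplan_meier(sub_a$duration, sub_a$event), horizons)
      ci_b <- cumulative_incidence_at(
        kaplan_meier(sub_b$duration, sub_b$event), horizons)
      data.table(outcome = ep, stratum = stratum, level = level,
                 horizon = ci_a$horizon,
                 cuminc = ci_a$cuminc, lower = ci_a$lower,
                 upper = ci_a$upper,
                 ref_cuminc = ci_b$cuminc, ref_lower = ci_b$lower,
                 ref_upper = ci_b$upper,
                 excess = excess_risk(ci_a$cuminc, ci_b$cuminc))
    }
    rows[[length(rows) + 1L]] <-
      add_rows(arm_sp[[1]], arm_sp[[2]], "all", "all")
    for (b in levels(strata_of$age_band)) {
      rows[[length(rows) + 1L]] <- add_rows(arm_sp[[1]][age_band == b],
                                            arm_sp[[2]][age_band == b],
                                            "age", b)
    }
    for (sx in sort(unique(strata_of$sex))) {
      rows[[length(rows) + 1L]] <- add_rows(arm_sp[[1]][sex == sx],
                                            arm_sp[[2]][sex == sx],
                                            "sex", sx)
    }
  }
  rbindlist(Filter(Negate(is.null), rows))
}

## ---------------------------------------------------------------------
## run the whole study
## ---------------------------------------------------------------------

#' Run the complete study end to end
#'
#' Generates (or accepts) the synthetic records, builds the cohorts and
#' matched controls, and runs the four analysis sets -- past-use bias
#' analysis, current-use comparison with stratifications, smoothed
#' duration-of-use hazard ratio, Kaplan-Meier life tables with excess
#' risks -- plus the cause-of-death table.  Deterministic under the
#' scenario seed.
#'
#' @param config A [scenario_config()].
#' @param out_dir Optional directory for report files (see
#'   [render_reports()]).
#' @param tables Optional pre-generated tables (from [simulate_ehr()]);
#'   generated from `config` when omitted.
#' @param match_seed Seed for control matching (default derived from the
#'   scenario seed).
#' @return A `study_results` list: `tables`, `cohorts`, `bias`, `gate`,
#'   `current_use`, `duration`, `life_tables`, `cause_of_death`, `log`.
#' @export
run_study <- function(config, out_dir = NULL, tables = NULL,
                      match_seed = NULL) {
  if (is.null(tables)) tables <- simulate_ehr(config)
  setattr(tables, "config", config)
  log <- list()
  log$patients <- nrow(tables$patients)

  overall <- build_exposed_cohort(tables$patients, tables$prescriptions)
  controls <- match_controls(overall, tables$patients,
                             tables$prescriptions,
                             seed = match_seed %||%
                               sub_seed(config$seed, 9L))
  cohorts <- list(overall = overall, controls = controls)
  for (cl in drug_classes())
    cohorts[[cl]] <- build_inception_cohort(tables$patients,
                                            tables$prescriptions, cl)
  log$exposed <- nrow(overall)
  log$controls <- nrow(controls)
  log$unmatched <- length(attr(controls, "unmatched"))

  bias <- run_bias_analysis(tables, cohorts)
  gate <- bias_gate(tables, cohorts)
  current_use <- run_current_use_comparison(tables, gate = gate)
  duration <- run_duration_analysis(tables)
  life_tables <- run_life_table_analysis(tables)
  cause_of_death <- tryCatch(run_cause_of_death(tables),
                             error = function(e) not_estimable(
                               conditionMessage(e)))

  results <- structure(
    list(config = config, tables = tables, cohorts = cohorts, bias = bias,
         gate = gate, current_use = current_use, duration = duration,
         life_tables = life_tables, cause_of_death = cause_of_death,
         log = log),
    class = "study_results")
  if (!is.null(out_dir)) render_reports(results, out_dir)
  results
}

#' Render deterministic report tables
#'
#' Writes the analysis outputs as comma-separated report files mirroring
#' the study's table layout: `table2_bias.csv`,
#' `table3_current_use.csv`, `table4_stratified.csv`,
#' `table5_cause_of_death.csv`, `table6_life_tables.csv`,
#' `hazard_curve.csv`, plus `run_log.csv` and a manifest.  Missing
#' analyses produce placeholder files so a partial run still renders.
#' Excess-risk cells are computed from unrounded life-table values;
#' values are written at full precision and rounded only for display.
#'
#' @param results A `study_results` object (possibly partial).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
render_reports <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  placeholder <- data.table(note = "analysis not run")
  w <- function(x, f) {
    fwrite(if (is.null(x) || inherits(x, "not_estimable")) placeholder
           else as.data.table(x),
           file.path(out_dir, f), dateTimeAs = "ISO")
    f
  }
  files <- c(
    w(results$bias, "table2_bias.csv"),
    w(results$current_use$main, "table3_current_use.csv"),
    w(results$current_use$stratified, "table4_stratified.csv"),
    w(results$cause_of_death, "table5_cause_of_death.csv"),
    w(results$life_tables, "table6_life_tables.csv"),
    w(results$duration, "hazard_curve.csv"),
    w(data.table(step = names(results$log),
                 count = unlist(results$log)), "run_log.csv"))
  if (!is.null(results$config))
    write_manifest(results$config, out_dir)
  invisible(files)
}

#' @export
print.study_results <- function(x, ...) {
  cat("<study_results>\n")
  cat(sprintf("  %d patients; %d exposed, %d matched controls (%d unmatched)\n",
              x$log$patients, x$log$exposed, x$log$controls, x$log$unmatched))
  if (!is.null(x$gate))
    cat(sprintf("  past-use gate (%s vs %s, %s): RR %.2f (%.2f-%.2f) -> %s\n",
                x$gate$drug_class, x$gate$reference, x$gate$outcome,
                x$gate$RR, x$gate$lower, x$gate$upper,
                if (x$gate$passed) "comparable" else "flagged"))
  inv <- x$current_use$main
  if (!is.null(inv) && nrow(inv)) {
    r <- inv[outcome == "death" & source == "gp" & adjustment == "full"]
    if (nrow(r))
      cat(sprintf("  current-use death RR (full adj): %.2f (%.2f-%.2f)\n",
                  r$RR, r$lower, r$upper))
  }
  invisible(x)
}
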