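## Cohort construction: prevalent-user overall cohort, per-class inception
## (new-user) cohorts, and matched non-diabetic controls.
##
## Date comparisons use half-open intervals and the inclusive boundary
## convention "one year after" = index >= data_start + 365 days.

ONE_YEAR_RUN_IN <- 365L

censor_of <- function(data_end, death_date) {
  pmin(data_end, fifelse(is.na(death_date), data_end, death_date + 1L))
}

#' Build the overall exposed cohort
#'
#' One entry per adult aged `min_age`+ whose first prescription for any
#' antidiabetic drug at least one year after start of data collection (and
#' at qualifying age) defines the index date; earlier prescriptions do not
#' qualify but remain in the exposure history (prevalent-user cohort).
#' Patients flagged type-1 diabetic are excluded.  Follow-up ends at
#' transfer out / last data collection or the day after death.
#'
#' @param patients,prescriptions Generator-shaped tables.
#' @param min_age Minimum age at index (years), default 40.
#' @return `data.table` of cohort entries (patient_id, cohort,
#'   index_date, censor_date).
#' @export
build_exposed_cohort <- function(patients, prescriptions, min_age = 40) {
  pat <- as.data.table(patients)
  rxe <- expand_rx(as.data.table(prescriptions))
  check_referential(pat, rxe)
  rxp <- pat[, .(patient_id, data_start, data_end, death_date, birth_year,
                 type1)][rxe, on = "patient_id"]
  rxp <- rxp[!(type1)]
  rxp <- rxp[as.numeric(date - data_start) >= ONE_YEAR_RUN_IN &
               age_at(birth_year, date) >= min_age]
  idx <- rxp[, .(index_date = min(date)), by = patient_id]
  idx <- pat[, .(patient_id, data_end, death_date)][idx, on = "patient_id"]
  idx[, censor_date := censor_of(data_end, death_date)]
  out <- idx[censor_date > index_date,
             .(patient_id, cohort = "overall_exposed", index_date,
               censor_date)]
  setorder(out, patient_id)
  out[]
}

#' Build a per-class inception (new-user) cohort
#'
#' A patient enters iff their first-ever prescription of `drug_class`
#' falls at least one year after start of data collection (inclusive
#' boundary) at qualifying age; prior prescriptions of other classes do
#' not exclude, so a patient may belong to several inception cohorts.
#' Multi-constituent preparations count towards every constituent class.
#'
#' @inheritParams build_exposed_cohort
#' @param drug_class One of [drug_classes()].
#' @return `data.table` of cohort entries with cohort label
#'   `"inception:<class>"`.
#' @export
build_inception_cohort <- function(patients, prescriptions, drug_class,
                                   min_age = 40) {
  if (!drug_class %in% drug_classes())
    stop_config("unknown drug class '%s'", drug_class)
  pat <- as.data.table(patients)
  rxe <- expand_rx(as.data.table(prescriptions))
  check_referential(pat, rxe)
  cls <- drug_class
  first_ever <- rxe[drug_class == cls, .(index_date = min(date)),
                    by = patient_id]
  first_ever <- pat[first_ever, on = "patient_id"]
  first_ever <- first_ever[!(type1)]
  first_ever <- first_ever[
    as.numeric(index_date - data_start) >= ONE_YEAR_RUN_IN &
      age_at(birth_year, index_date) >= min_age]
  first_ever[, censor_date := censor_of(data_end, death_date)]
  out <- first_ever[censor_date > index_date,
                    .(patient_id, cohort = paste0("inception:", cls),
                      index_date, censor_date)]
  setorder(out, patient_id)
  out[]
}

check_referential <- function(pat, rxe) {
  unknown <- setdiff(unique(rxe$patient_id), pat$patient_id)
  if (length(unknown))
    stop_config("prescriptions reference unknown patients: %s",
                paste(head(unknown, 5L), collapse = ", "))
}

#' Matching criteria for control selection
#'
#' @param age_tolerance Maximum absolute age difference in years.
#' @param match_on Matching variables; sex and practice are always exact.
#' @return A `match_criteria` list.
#' @export
match_criteria <- function(age_tolerance = 5,
                           match_on = c("sex", "practice")) {
  if (age_tolerance < 0) stop_config("age_tolerance must be >= 0")
  structure(list(age_tolerance = age_tolerance, match_on = match_on,
                 same_index_date = TRUE),
            class = "match_criteria")
}

#' Match one control per exposed patient
#'
#' Each exposed patient is matched to at most one control from the same
#' practice and sex, within the age tolerance, alive and under observation
#' at the exposed patient's index date, with no antidiabetic prescription
#' before that date.  The control inherits the exposed patient's index
#' date.  Among eligible candidates the nearest in age is chosen, ties
#' broken by a seeded random draw; each control serves at most one exposed
#' patient.  Unmatched exposed patients are reported in the `unmatched`
#' attribute, not dropped from their own cohort.
#'
#' A matched control's follow-up is censored at their first antidiabetic
#' prescription, if any, so control person-time never contains exposed
#' time.
#'
#' @param exposed Cohort entries to match (e.g. the overall exposed
#'   cohort).
#' @param patients,prescriptions Generator-shaped tables.
#' @param criteria A [match_criteria()].
#' @param seed Integer seed for tie-breaking.
#' @return `data.table` of control cohort entries (cohort `"control"`,
#'   `matched_to` = exposed patient_id), with attribute `unmatched`.
#' @export
match_controls <- function(exposed, patients, prescriptions,
                           criteria = match_criteria(), seed = 1L) {
  stopifnot(inherits(criteria, "match_criteria"))
  set.seed(as.integer(seed) %% 2147483647)
  pat <- as.data.table(patients)
  exp_dt <- as.data.table(exposed)
  rxe <- expand_rx(as.data.table(prescriptions))
  first_rx <- rxe[, .(first_rx = min(date)), by = patient_id]

  cand <- pat[!patient_id %in% exp_dt$patient_id]
  cand <- first_rx[cand, on = "patient_id"]
  exp_info <- pat[, .(patient_id, practice_id, sex, birth_year)][
    exp_dt, on = "patient_id"]
  exp_info[, age_idx := age_at(birth_year, index_date)]
  setorder(exp_info, index_date, patient_id)

  ## candidate pools keyed by (practice, sex)
  cand[, key := paste(practice_id, sex)]
  pools <- split(cand, by = "key", keep.by = TRUE)
  taken <- new.env(hash = TRUE, parent = emptyenv())

  rows <- vector("list", nrow(exp_info))
  unmatched <- integer(0)
  for (i in seq_len(nrow(exp_info))) {
    e <- exp_info[i]
    pool <- pools[[paste(e$practice_id, e$sex)]]
    if (is.null(pool)) { unmatched <- c(unmatched, e$patient_id); next }
    ok <- pool[data_start <= e$index_date & data_end > e$index_date &
                 (is.na(death_date) | death_date > e$index_date) &
                 (is.na(first_rx) | first_rx > e$index_date)]
    if (nrow(ok)) {
      free <- !vapply(as.character(ok$patient_id),
                      function(k) !is.null(taken[[k]]), TRUE)
      ok <- ok[free]
    }
    if (!nrow(ok)) { unmatched <- c(unmatched, e$patient_id); next }
    ok[, age_diff := abs(age_at(birth_year, e$index_date) - e$age_idx)]
    ok <- ok[age_diff <= criteria$age_tolerance]
    if (!nrow(ok)) { unmatched <- c(unmatched, e$patient_id); next }
    best <- ok[age_diff == min(age_diff)]
    pick <- best[if (nrow(best) == 1L) 1L else sample.int(nrow(best), 1L)]
    taken[[as.character(pick$patient_id)]] <- TRUE
    censor <- censor_of(pick$data_end, pick$death_date)
    if (!is.na(pick$first_rx)) censor <- pmin(censor, pick$first_rx)
    rows[[i]] <- data.table(patient_id = pick$patient_id,
                            cohort = "control",
                            index_date = e$index_date,
                            censor_date = censor,
                            matched_to = e$patient_id)
  }
  out <- rbindlist(rows)
  if (!nrow(out))
    out <- data.table(patient_id = integer(0), cohort = character(0),
                      index_date = as.Date(character(0)),
                      censor_date = as.Date(character(0)),
                      matched_to = integer(0))
  out <- out[censor_date > index_date]
  setattr(out, "unmatched", unmatched)
  out[]
}
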